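# possumval

External validation and recalibration of POSSUM-family surgical mortality
scores.

POSSUM (Physiological and Operative Severity Score for the enUmeration of
Mortality and morbidity) and its Portsmouth refinement P-POSSUM predict
30-day post-operative mortality from two integer scores — a physiological
score PS (12 factors graded 1/2/4/8, range 12–96) and an operative severity
score OS (6 factors, range 6–48) — through linear-logistic equations:

```
POSSUM:    ln[R/(1-R)] = -7.04  + 0.13   PS + 0.16  OS
P-POSSUM:  ln[R/(1-R)] = -9.065 + 0.1692 PS + 0.155 OS
S-POSSUM:  ln[R/(1-R)] = -6.505 + 0.144  PS + 0.03  OS + 1.057 NE
```

(NE = 1 for non-elective surgery). Surgical units use these scores for
audit: does the model *discriminate* (rank non-survivors above survivors,
measured by the C-statistic/AUC) and is it *calibrated* (do observed deaths
match expected deaths across the risk range, measured by risk-banded
observed:expected ratios and the Hosmer–Lemeshow chi-square)? A unit whose
observed mortality falls well below prediction — overall O:E far under 1 —
either outperforms the reference population or needs a recalibrated score.

`possumval` is a toolkit for exactly this audit, aimed at perioperative
researchers and audit teams:

* **scoring** — the three predefined models, arbitrary `risk_model()`
  constants, score validation and the standard eligibility filter;
* **discrimination** — ROC curves and AUC (Mann–Whitney concordance,
  Hanley–McNeil SE);
* **calibration** — equal-width ("deciles of risk") and
  equal-expected-deaths banding, per-band and total Hosmer–Lemeshow
  statistics, O:E ratios with exact Poisson intervals, calibration curves
  with exact binomial intervals;
* **recalibration** — logistic refit of mortality on PS, OS and urgency by
  Newton–Raphson maximum likelihood, with a Wald coefficient/odds-ratio
  table and the refit packaged as a new risk model (the S-POSSUM
  procedure);
* **synthetic cohorts** — a seeded simulator with a controllable
  logit-scale miscalibration, so the pipeline runs without patient data;
* **interface** — cohort CSV I/O, JSON/markdown report writers, and a thin
  command-line front end (`possumval_cli()`, installed at
  `inst/scripts/possumval`).

## Worked example

```r
library(possumval)

# one patient: POSSUM risk for PS 20, OS 14
predicted_risk(possum_model(), ps = 20, os = 14)
#> [1] 0.09975049

# a synthetic level-1-care audit cohort (2552 episodes, seeded)
ch <- generate_cohort(default_cohort_spec())
ch
#> <cohort> 2552 episodes, 84 deaths (3.29%) [synthetic (truth=level1-truth, lambda=0.0684, slope=1, seed=20080630)]

rep <- run_validation(ch, possum_model())
rep
#> External validation of POSSUM on synthetic (truth=level1-truth, lambda=0.0684, slope=1, seed=20080630) (eligible)
#>   episodes: 2552 eligible (0 incomplete, 0 indirect excluded)
#>   discrimination: AUC = 0.805 +/- 0.029 SE (good_to_excellent)
#>   overall O:E = 0.24 (0.19 - 0.30); observed 84, expected 346.89
#>   HL (deciles of risk): chi-square = 331.60, df = 8, p < 0.0001 [poor fit]
```

Read: POSSUM ranks these patients well (AUC 0.805) but expects 346.9 deaths
where 84 occurred — it overpredicts fourfold (O:E 0.24, CI excluding 1),
and the decile-wise Hosmer–Lemeshow test rejects calibration outright.
That is the classic indication for recalibration:

```r
rec <- derive_recalibrated_model(apply_eligibility(ch)$eligible)
rec$model
#> <risk_model> recalibrated
#>   ln[R/(1-R)] = -9.52109 +0.118057 x PS +0.170572 x OS +1.87371 x NE
rec$hl
#> Hosmer-Lemeshow (equal_expected bands): chi-square = 9.32; df = 8; p = 0.32
```

The refit shows no lack of fit on its cohort (p = 0.32), and
`write_model_json()` / `read_model_json()` feed it back into the scoring
pipeline. `write_validation_report()` emits `report.json`,
`calibration.md` (the banded audit tables at two decimals) and
`roc_points.csv`.

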