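---
title: "Validating and recalibrating POSSUM-family surgical risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and recalibrating POSSUM-family surgical risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(possumval)
```

## The models

POSSUM summarises a surgical patient as two integers: a physiological score
PS (12 factors, each graded 1, 2, 4 or 8, so PS ranges 12–96) and an
operative severity score OS (6 factors, range 6–48). Mortality risk is a
linear-logistic function of the two:

* POSSUM: $\ln\frac{R}{1-R} = -7.04 + 0.13\,PS + 0.16\,OS$
* P-POSSUM: $\ln\frac{R}{1-R} = -9.065 + 0.1692\,PS + 0.155\,OS$
* S-POSSUM: $\ln\frac{R}{1-R} = -6.505 + 0.144\,PS + 0.03\,OS + 1.057\,NE$

where $NE = 1$ for non-elective (emergency) surgery. S-POSSUM is the kind of
model this package's recalibration module produces: a refit of the outcome
on PS, OS and urgency in a local cohort. The package consumes PS and OS as
integers; grading raw physiology into factor scores is out of scope.

A note on the urgency sign: S-POSSUM is stated here in the NE = non-elective
convention with a positive coefficient, which is the direction the data
demand (emergency mortality is several-fold elective mortality). Reports
produced by reverse-coded software print the same magnitude with a negative
sign for an "Emergency" row; `derive_recalibrated_model(reverse_urgency =
TRUE)` reproduces that parameterisation and converts it back to the same
risk model.

## External validation

`run_validation()` chains the audit steps:

1. **Eligibility.** Episodes with incomplete data or not directly admitted
   to the unit are excluded; an episode failing both is counted once, under
   incomplete data, so per-reason counts sum to the number excluded.
2. **Discrimination.** The C-statistic is the Mann–Whitney concordance
   (ties count 1/2), and the reported curve is a descending threshold sweep
   whose trapezoidal area equals the concordance identically — the suite
   checks this equivalence against a brute-force all-pairs oracle. The
   standard error is Hanley–McNeil; other choices (DeLong) exist, and the
   method is recorded in the report metadata.
3. **Calibration.** Two banding schemes: *equal width* (deciles of risk,
   $[i/k, (i+1)/k)$, final band closed) and *equal expected deaths*
   (episodes sorted by risk; cuts where cumulative expected deaths reach
   $j/k$ of the total; tied risks are never split — the whole tie group
   follows its lowest-ranked member). Each band reports observed and
   expected deaths, mean predicted risk, O:E with an exact interval, and
   its Hosmer–Lemeshow component
   $(O-E)^2/E + ((N-O)-(N-E))^2/(N-E) = (O-E)^2/\{E(1-E/N)\}$.
4. **Overall O:E.** Observed over expected deaths with an exact Poisson
   (Garwood) interval on the numerator, expected treated as fixed — the
   standardised-mortality-ratio convention. Simulation in the test suite
   puts its coverage at ~95% for Poisson counts; for binomial outcomes it
   over-covers slightly (binomial counts are underdispersed), which is the
   conservative direction for an audit.

### Hosmer–Lemeshow degrees of freedom

`hl_test()` defaults to $df = g - 2$ for $g$ non-empty bands, the
convention of audit reports (10 bands, df 8) inherited from the original
test for models fitted to the data at hand. For a *pre-specified external*
model the component sum is approximately $\chi^2_g$, not $\chi^2_{g-2}$;
using $g-2$ there roughly doubles the nominal type-I error (we measure
0.103 instead of 0.05 at $\alpha = 0.05$). The package keeps the reporting
convention as the default for comparability and exposes
`df = "external"` for the statistically calibrated reference; the
null-rejection property tests use the external reference, where the
measured rate is 0.050 over 1000 simulated cohorts of n = 2000.

Empty bands are retained in tables as zero rows but excluded from the
statistic and its df (the component is undefined at $E = 0$). Degenerate
bands with $E \ge N$ cannot arise from risks strictly inside (0, 1).

## Recalibration

`fit_logistic()` is a Newton–Raphson maximiser of the binomial
log-likelihood with step-halving, so the log-likelihood is non-decreasing
across iterations. Convergence is declared when the score max-norm falls
below 1e-8 (a likelihood-change criterion alone can stop short of the
optimum by more than the oracle tolerance; even `summary.glm`'s standard
errors at default tolerance differ from the converged values by ~1e-5).
Standard errors come from the inverse observed information; inference is
Wald (the symmetric-in-log CIs of clinical coefficient tables).
Coefficients exceeding |b| = 30 on any iteration raise a separation error
rather than returning a divergent fit. Because the score equations force
$\sum \hat p_i = \sum y_i$, a refit is always calibrated-in-the-large on
its own training data; its HL test (equal-expected bands, df $g-2$ — here
the model *is* fitted, so the classic convention applies) measures
calibration across the risk range.

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()` emulates
the statistical structure the pipeline assumes. Per episode it draws PS and
OS from discretized, truncated log-normal weight vectors, urgency as
Bernoulli, specialty from a fixed mix, and the 30-day outcome from
$\mathrm{logit}^{-1}\{\ln\lambda + s \cdot L_{truth}\}$, where $L_{truth}$
is the truth model's linear predictor. The distortion $(\lambda, s)$ is the
standard logit-scale miscalibration framework: $\lambda$ is a uniform odds
multiplier (calibration-in-the-large), $s$ a calibration slope;
$\lambda = s = 1$ makes the truth model exactly calibrated. PS and OS are
independent by default, with a Gaussian-copula rank-correlation knob, since
real physiological and operative scores plausibly correlate.

`default_cohort_spec()` packages one fixed set of study conditions:
n = 2552 episodes, 24.5% non-elective, specialty mix 56.3/31.7/11.7/0.7%.
The remaining constants were solved once, numerically and deterministically,
from four published marginal targets: the score distributions
(PS ~ lognormal(2.838, 0.40), OS ~ lognormal(2.519, 0.35)) match the mean
POSSUM-predicted risk (350.94/2552 = 0.1375) and mean P-POSSUM risk
(162.35/2552 = 0.0636); the truth model (POSSUM coefficients plus urgency
log-odds 2.049, $\lambda = 0.0684$) matches elective mortality 33/1926 and
emergency mortality 55/626. Nothing else about the real cohort is known, so
these defaults reproduce its margins, not its joint distribution: under
them a POSSUM audit yields AUC ≈ 0.80 and overall O:E ≈ 0.24, and a
P-POSSUM audit O:E ≈ 0.53 — the overprediction regime the pipeline is
designed to detect — but absolute AUCs and per-band tallies depend on the
unobserved score histogram and are asserted only directionally in tests.
Passing tests on synthetic cohorts therefore demonstrate correctness of the
statistical machinery, not agreement with any particular hospital's case
mix; real data can also violate the generator's assumptions (independent
episodes, no score-urgency interaction beyond the NE term, time-constant
risk).

Generation is seeded and byte-reproducible; the generator saves and
restores the caller's RNG state.

## Numerical choices and problem sizes

* Risks are never rounded internally; tables render at two decimals
  (half-up) only in writers.
* Band edges are half-open, final band closed; a risk of exactly 0.10
  falls in the 10–20% decile.
* Exact intervals: Garwood (chi-square form) for O:E, Clopper–Pearson
  (beta form) for band death rates.
* Test-suite simulation sizes were chosen as the smallest that make the
  checked contrasts unambiguous: 1000 replicates for type-I error and CI
  coverage, n = 50,000 for a single parameter-recovery fit (all
  coefficients within 3 estimated SEs of truth), n = 2000–10,000 cohorts
  for calibration contrasts, 20 seeds for the AUC dominance check.

## Known limitations

* Per-band O:E intervals published in some audit tables are narrower than
  any standard Poisson/binomial interval produces; the package documents
  its interval method in report metadata rather than matching any
  particular table's unstated one.
* No DeLong AUC comparison, confidence bands on ROC curves, Brier score,
  Spiegelhalter's z, penalised/Firth regression, or bootstrap optimism
  correction.
* Morbidity outcomes, length of stay and grading of raw physiology are out
  of scope.
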