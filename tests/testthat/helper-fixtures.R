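# in-code fixtures shared across test files

# minimal valid episode table; defaults give an eligible elective episode
make_episodes <- function(n, ps = 20, os = 12, urgency = "elective",
                          specialty = "general_surgery", died = 0,
                          direct = TRUE, complete = TRUE) {
  data.frame(ps = rep_len(ps, n), os = rep_len(os, n),
             urgency = rep_len(urgency, n),
             specialty = rep_len(specialty, n),
             died_30d = rep_len(died, n),
             directly_admitted = rep_len(direct, n),
             data_complete = rep_len(complete, n))
}

# a small mixed cohort with both outcome classes and both urgencies
toy_cohort <- function(n = 200, seed = 11) {
  set.seed(seed)
  ep <- make_episodes(n,
                      ps = sample(12:60, n, TRUE),
                      os = sample(6:30, n, TRUE),
                      urgency = sample(c("elective", "non_elective"), n, TRUE),
                      died = rbinom(n, 1, 0.2))
  cohort(ep, provenance = "toy")
}

# brute-force all-pairs concordance oracle for the AUC
pairwise_auc <- function(risks, outcomes) {
  d <- risks[outcomes == 1]
  s <- risks[outcomes == 0]
  sc <- 0
  for (x in d) for (y in s)
    sc <- sc + if (x > y) 1 else if (x == y) 0.5 else 0
  sc / (length(d) * length(s))
}

# hand-built band table (for exercising hl_test on known components)
fake_bands <- function(components, n = 100, e = 10, o = 10) {
  k <- length(components)
  b <- data.frame(lower = (0:(k - 1)) / k, upper = (1:k) / k,
                  n_patients = rep(n, k), observed_deaths = rep(o, k),
                  expected_deaths = rep(e, k), mean_risk = rep(e / n, k),
                  oe_ratio = rep(o / e, k), oe_low = NA_real_,
                  oe_high = NA_real_, hl_component = components)
  structure(b, scheme = "equal_width", class = c("risk_bands", "data.frame"))
}
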