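# Calibration: risk banding, Hosmer-Lemeshow components and totals,
# observed:expected mortality ratios, calibration tables and curves.

#' Hosmer-Lemeshow group component
#'
#' The two-cell chi-square term for one risk band with `n` patients,
#' `o` observed deaths and `e` expected deaths:
#' \deqn{(O-E)^2/E + ((N-O)-(N-E))^2/(N-E),}
#' algebraically equal to \eqn{(O-E)^2 / (E(1-E/N))}.
#'
#' @param n Patients in the band.
#' @param o Observed deaths in the band.
#' @param e Expected deaths (sum of predicted risks) in the band.
#' @return The component value (vectorised).
#' @examples
#' hl_component(1501, 15, 71.96)  # 47.36
#' @export
hl_component <- function(n, o, e) {
  if (any(e <= 0 | e >= n))
    stop_stat("degenerate band: expected deaths must lie strictly between ",
              "0 and n (merge the band into a neighbour)")
  if (any(o < 0 | o > n)) stop("observed deaths must lie in [0, n]", call. = FALSE)
  (o - e)^2 / e + ((n - o) - (n - e))^2 / (n - e)
}

#' Observed:expected mortality ratio with exact Poisson interval
#'
#' Ratio of observed to model-expected deaths. The confidence interval is the
#' exact (Garwood) Poisson interval for the observed count, divided by the
#' expected count, which is treated as fixed -- the convention used for
#' standardised mortality ratios. The lower bound is 0 when no deaths were
#' observed.
#'
#' @param o Observed death count.
#' @param e Expected deaths (> 0).
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `ratio`, `low`, `high`.
#' @examples
#' oe_ratio(88, 350.94)  # 0.25, the POSSUM overall O:E
#' @export
oe_ratio <- function(o, e, level = 0.95) {
  stopifnot(length(o) == 1L, length(e) == 1L, o >= 0, o == round(o),
            level > 0, level < 1)
  if (e <= 0) stop_stat("expected deaths must be positive")
  a <- 1 - level
  low <- if (o == 0) 0 else stats::qchisq(a / 2, 2 * o) / 2 / e
  high <- stats::qchisq(1 - a / 2, 2 * (o + 1)) / 2 / e
  c(ratio = o / e, low = low, high = high)
}

# Build the per-band summary table from an episode->band assignment.
# Empty bands are kept as zero rows (report fidelity) with NA O:E and HL.
summarize_bands <- function(risk, outcome, band_idx, lower, upper, level = 0.95) {
  k <- length(lower)
  rows <- lapply(seq_len(k), function(i) {
    sel <- band_idx == i
    n <- sum(sel)
    o <- sum(outcome[sel])
    e <- sum(risk[sel])
    mean_risk <- if (n > 0) mean(risk[sel]) else NA_real_
    if (n > 0 && e > 0) {
      oe <- oe_ratio(o, e, level)
      hl <- hl_component(n, o, e)
    } else {
      oe <- c(ratio = NA_real_, low = NA_real_, high = NA_real_)
      hl <- NA_real_
    }
    data.frame(lower = lower[i], upper = upper[i], n_patients = n,
               observed_deaths = o, expected_deaths = e, mean_risk = mean_risk,
               oe_ratio = unname(oe["ratio"]), oe_low = unname(oe["low"]),
               oe_high = unname(oe["high"]), hl_component = hl)
  })
  do.call(rbind, rows)
}

#' Equal-width risk bands (deciles of risk)
#'
#' Partitions scored episodes into `k` bands of predicted risk
#' \eqn{[i/k, (i+1)/k)}, the final band closed at 1 ("deciles of risk" when
#' `k = 10`). Empty bands are retained as zero rows but carry no
#' Hosmer-Lemeshow component and do not count towards its degrees of freedom.
#'
#' @param pairs Data frame with columns `risk` and `outcome`
#'   (from [score_cohort()]).
#' @param k Number of bands, at least 2 (default 10).
#' @param level Confidence level for per-band O:E intervals.
#' @return A data frame of class \code{risk_bands}, one row per band, with
#'   columns `lower`, `upper`, `n_patients`, `observed_deaths`,
#'   `expected_deaths`, `mean_risk`, `oe_ratio`, `oe_low`, `oe_high`,
#'   `hl_component`.
#' @export
band_equal_width <- function(pairs, k = 10, level = 0.95) {
  check_pairs(pairs)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop("k must be an integer >= 2", call. = FALSE)
  k <- as.integer(k)
  idx <- pmin(floor(pairs$risk * k), k - 1L) + 1L
  bands <- summarize_bands(pairs$risk, pairs$outcome, idx,
                           lower = (0:(k - 1)) / k, upper = (1:k) / k, level)
  structure(bands, scheme = "equal_width", class = c("risk_bands", "data.frame"))
}

#' Equal-expected-deaths risk bands
#'
#' Sorts episodes by ascending predicted risk and places cut points where
#' cumulative expected deaths first reach \eqn{j/k} of the total, so each
#' band carries (as nearly as possible) the same predicted death count. Tied
#' risks are never split across bands: the whole tie group takes the band of
#' its lowest-ranked member. A warning is issued when expected deaths per
#' band fall below 5, where the chi-square approximation weakens.
#'
#' @inheritParams band_equal_width
#' @return A \code{risk_bands} data frame; band boundaries are the observed
#'   risk ranges.
#' @export
band_equal_expected <- function(pairs, k = 10, level = 0.95) {
  check_pairs(pairs)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop("k must be an integer >= 2", call. = FALSE)
  k <- as.integer(k)
  if (k > length(unique(pairs$risk)))
    stop("k exceeds the number of distinct risk values", call. = FALSE)
  ord <- order(pairs$risk)
  r <- pairs$risk[ord]
  y <- pairs$outcome[ord]
  total_e <- sum(r)
  if (total_e < 5 * k)
    warning(sprintf(
      "expected deaths per band (%.2f) below 5; chi-square approximation may be poor",
      total_e / k), call. = FALSE)
  thresholds <- total_e * seq_len(k - 1) / k
  cum_e <- cumsum(r)
  idx <- 1L + vapply(cum_e, function(ce) sum(thresholds <= ce), 0L)
  idx <- pmin(idx, k)
  # tie groups stay together: whole group takes its first member's band
  first_of_group <- ave(idx, match(r, unique(r)), FUN = function(v) v[1])
  idx <- as.integer(cummax(first_of_group))
  # band boundaries: observed risk ranges per occupied band
  lower <- upper <- rep(NA_real_, k)
  for (i in unique(idx)) {
    lower[i] <- min(r[idx == i])
    upper[i] <- max(r[idx == i])
  }
  bands <- summarize_bands(r, y, idx, lower, upper, level)
  structure(bands, scheme = "equal_expected",
            class = c("risk_bands", "data.frame"))
}

check_pairs <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("risk", "outcome") %in% names(pairs)))
    stop("pairs must be a data frame with columns 'risk' and 'outcome'",
         call. = FALSE)
  if (nrow(pairs) == 0L) stop("pairs must be non-empty", call. = FALSE)
  if (any(pairs$risk <= 0 | pairs$risk >= 1))
    stop("risks must lie strictly inside (0, 1)", call. = FALSE)
  if (!all(pairs$outcome %in% c(0, 1)))
    stop("outcomes must be binary 0/1", call. = FALSE)
  invisible(TRUE)
}

#' Hosmer-Lemeshow goodness-of-fit test over risk bands
#'
#' Sums the per-band components over non-empty bands and refers the total to
#' a chi-square distribution. By convention (shared with standard risk-score
#' audits) the default degrees of freedom are \eqn{g - 2} for \eqn{g}
#' non-empty bands, the reference appropriate when the model was fitted to
#' the data at hand. For a fully pre-specified external model the component
#' sum is approximately chi-square with \eqn{g} degrees of freedom; pass
#' `df = "external"` (or a number) for that reference.
#'
#' @param bands A \code{risk_bands} data frame.
#' @param df `"fitted"` (default, \eqn{g-2}), `"external"` (\eqn{g}), or an
#'   explicit integer.
#' @param alpha Poor-fit flag threshold on the p-value (default 0.05).
#' @return An object of class \code{hl_result}: list with `statistic`, `df`,
#'   `p_value`, `n_bands`, `poor_fit`, `scheme`, and the `bands` table.
#' @examples
#' # a statistic of 4.503 on 8 df corresponds to p = 0.81
#' stats::pchisq(4.503, 8, lower.tail = FALSE)
#' @export
hl_test <- function(bands, df = c("fitted", "external"), alpha = 0.05) {
  stopifnot(inherits(bands, "risk_bands"))
  nonempty <- bands$n_patients > 0 & bands$expected_deaths > 0
  g <- sum(nonempty)
  if (g < 3) stop_stat("Hosmer-Lemeshow test needs at least 3 non-empty bands")
  if (is.character(df)) {
    df <- match.arg(df)
    df_val <- if (df == "fitted") g - 2L else g
  } else {
    stopifnot(is.numeric(df), length(df) == 1L, df >= 1)
    df_val <- as.integer(df)
  }
  statistic <- sum(bands$hl_component[nonempty])
  p <- stats::pchisq(statistic, df_val, lower.tail = FALSE)
  structure(list(statistic = statistic, df = df_val, p_value = p,
                 n_bands = g, poor_fit = p <= alpha,
                 scheme = attr(bands, "scheme"), bands = bands),
            class = "hl_result")
}

#' @export
print.hl_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow (%s bands): chi-square = %.2f; df = %d; p %s\n",
              x$scheme, x$statistic, x$df,
              if (x$p_value < 1e-4) "< 0.0001" else sprintf("= %.2g", x$p_value)))
  if (x$poor_fit) cat("  -> poor calibration (p <= 0.05)\n")
  invisible(x)
}

#' Full calibration table for a model on a cohort
#'
#' Scores the cohort, bands it under the requested scheme, and assembles the
#' audit table: one row per risk band (patients, observed and expected
#' deaths, mean predicted risk, O:E with CI, Hosmer-Lemeshow component) plus
#' a pooled overall row and the Hosmer-Lemeshow total.
#'
#' @param model A [risk_model()].
#' @param chrt A [cohort()] (already eligibility-filtered).
#' @param scheme `"equal_width"` or `"equal_expected"`.
#' @param k Number of bands (default 10).
#' @param level Confidence level for O:E intervals.
#' @param df Degrees-of-freedom convention passed to [hl_test()].
#' @return An object of class \code{calibration_table}: list with `model`,
#'   `scheme`, `bands`, `hl` (an [hl_test()] result) and `overall` (pooled
#'   n, observed, expected, O:E with CI).
#' @export
calibration_table <- function(model, chrt, scheme = c("equal_width", "equal_expected"),
                              k = 10, level = 0.95, df = "fitted") {
  scheme <- match.arg(scheme)
  pairs <- score_cohort(model, chrt)
  bands <- switch(scheme,
                  equal_width = band_equal_width(pairs, k, level),
                  equal_expected = band_equal_expected(pairs, k, level))
  hl <- hl_test(bands, df = df)
  o <- sum(pairs$outcome)
  e <- sum(pairs$risk)
  oe <- oe_ratio(o, e, level)
  overall <- data.frame(n_patients = nrow(pairs), observed_deaths = o,
                        expected_deaths = e, mean_risk = mean(pairs$risk),
                        oe_ratio = unname(oe["ratio"]),
                        oe_low = unname(oe["low"]), oe_high = unname(oe["high"]))
  structure(list(model = model$name, scheme = scheme, k = k, bands = bands,
                 hl = hl, overall = overall),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(render_calibration_md(x), sep = "\n")
  invisible(x)
}

#' Calibration curve points from a band table
#'
#' Per non-empty band: mean predicted risk against the observed death rate
#' with an exact (Clopper-Pearson) binomial confidence interval. A perfectly
#' calibrated model lies on the line of unity.
#'
#' @param bands A \code{risk_bands} data frame.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `mean_risk`, `observed_rate`, `ci_low`, `ci_high`.
#' @export
calibration_curve <- function(bands, level = 0.95) {
  stopifnot(inherits(bands, "risk_bands"))
  if (nrow(bands) == 0L) stop("bands must be non-empty", call. = FALSE)
  keep <- bands$n_patients > 0
  if (!all(keep)) warning("skipping empty band(s)", call. = FALSE)
  b <- bands[keep, , drop = FALSE]
  a <- 1 - level
  n <- b$n_patients
  o <- b$observed_deaths
  ci_low <- ifelse(o == 0, 0, stats::qbeta(a / 2, o, n - o + 1))
  ci_high <- ifelse(o == n, 1, stats::qbeta(1 - a / 2, o + 1, n - o))
  data.frame(mean_risk = b$mean_risk, observed_rate = o / n,
             ci_low = ci_low, ci_high = ci_high)
}

#' @export
plot.calibration_table <- function(x, ...) {
  cc <- calibration_curve(x$bands)
  plot(cc$mean_risk, cc$observed_rate, xlim = c(0, 1), ylim = c(0, 1),
       pch = 19, xlab = "Mean predicted mortality risk",
       ylab = "Observed mortality", main = sprintf("Calibration: %s", x$model),
       ...)
  graphics::arrows(cc$mean_risk, cc$ci_low, cc$mean_risk, cc$ci_high,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

# presentation rounding: two decimals, half-up (computation stays unrounded)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

render_calibration_md <- function(tab) {
  b <- tab$bands
  fmt <- function(x, d = 2) ifelse(is.na(x), "-",
                                   sprintf(paste0("%.", d, "f"),
                                           round_half_up(x, d)))
  band_label <- if (tab$scheme == "equal_width")
    sprintf("%g-%g", 100 * b$lower, 100 * b$upper)
  else sprintf("%s-%s", fmt(100 * b$lower, 1), fmt(100 * b$upper, 1))
  header <- c(
    sprintf("Hosmer-Lemeshow goodness of fit for %s (%s bands)",
            tab$model, tab$scheme),
    "",
    paste("| Risk band (%) | Patients | Observed deaths | Expected deaths |",
          "Mean risk | O:E (95% CI) | HL component |"),
    "|---|---|---|---|---|---|---|")
  rows <- sprintf("| %s | %d | %d | %s | %s | %s (%s - %s) | %s |",
                  band_label, b$n_patients, b$observed_deaths,
                  fmt(b$expected_deaths), fmt(b$mean_risk),
                  fmt(b$oe_ratio), fmt(b$oe_low), fmt(b$oe_high),
                  fmt(b$hl_component))
  ov <- tab$overall
  total <- sprintf("| 0-100 | %d | %d | %s | %s | %s (%s - %s) | %s |",
                   ov$n_patients, ov$observed_deaths, fmt(ov$expected_deaths),
                   fmt(ov$mean_risk), fmt(ov$oe_ratio), fmt(ov$oe_low),
                   fmt(ov$oe_high), fmt(tab$hl$statistic))
  footer <- sprintf("HL statistic = %s; df = %d; p %s",
                    fmt(tab$hl$statistic), tab$hl$df,
                    if (tab$hl$p_value < 1e-4) "< 0.0001"
                    else sprintf("= %.2g", tab$hl$p_value))
  c(header, rows, total, "", footer)
}
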