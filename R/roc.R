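# Discrimination: ROC curve and C-statistic (AUC).

#' ROC curve and C-statistic for predicted risks
#'
#' The AUC is computed as the Mann-Whitney concordance: over all
#' death/survivor pairs, the fraction in which the death carries the higher
#' predicted risk, counting ties as 1/2. The curve itself is a threshold
#' sweep in descending risk, one point per distinct risk value plus the
#' (0,0) and (1,1) endpoints; its trapezoidal area equals the concordance
#' identically. The standard error uses the Hanley-McNeil formula (under
#' their binegative-exponential model).
#'
#' @param risks Numeric predicted risks in (0, 1) (any monotone score works;
#'   AUC is rank-based).
#' @param outcomes Binary outcomes, 1 = death.
#' @return An object of class \code{possum_roc}: list with `auc`, `auc_se`,
#'   `n_events`, `n_nonevents`, `points` (data frame of `fpr`, `tpr`), and
#'   `se_method`.
#' @examples
#' r <- roc_curve(c(.1, .4, .35, .8), c(0, 0, 1, 1))
#' r$auc  # 0.75
#' @export
roc_curve <- function(risks, outcomes) {
  if (!all(outcomes %in% c(0, 1)))
    stop("outcomes must be binary 0/1", call. = FALSE)
  if (length(risks) != length(outcomes))
    stop("risks and outcomes must have equal length", call. = FALSE)
  y <- as.integer(outcomes)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L) stop_stat("no deaths in input: AUC undefined")
  if (n0 == 0L) stop_stat("no survivors in input: AUC undefined")

  # Mann-Whitney via mid-ranks: ties contribute 1/2 per pair
  r <- rank(risks, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # threshold sweep, descending risk, one point per distinct value
  thr <- sort(unique(risks), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(y == 1L & risks >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(y == 0L & risks >= t) / n0, 0)
  points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (points$fpr[nrow(points)] != 1 || points$tpr[nrow(points)] != 1)
    points <- rbind(points, data.frame(fpr = 1, tpr = 1))

  # Hanley & McNeil SE
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))

  structure(list(auc = auc, auc_se = se, n_events = n1, n_nonevents = n0,
                 points = points, se_method = "Hanley-McNeil"),
            class = "possum_roc")
}

#' @export
print.possum_roc <- function(x, ...) {
  cat(sprintf("<roc> AUC = %.3f +/- %.3f SE (%s; %d deaths / %d survivors) - %s\n",
              x$auc, x$auc_se, x$se_method, x$n_events, x$n_nonevents,
              interpret_auc(x$auc)))
  invisible(x)
}

#' @export
plot.possum_roc <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Qualitative interpretation of an AUC
#'
#' Conventional discrimination bands: 0.5 has no discriminating value,
#' below 0.7 is poor, 0.7--0.8 acceptable, 0.8--0.9 good to excellent, and
#' 0.9 or above excellent.
#'
#' @param auc A number in \[0, 1\].
#' @return One of `"none"`, `"poor"`, `"acceptable"`, `"good_to_excellent"`,
#'   `"excellent"`.
#' @export
interpret_auc <- function(auc) {
  if (!is.numeric(auc) || length(auc) != 1L || is.na(auc) ||
      auc < 0 || auc > 1)
    stop("auc must be a single number in [0, 1]", call. = FALSE)
  if (auc == 0.5) return("none")
  if (auc >= 0.9) "excellent"
  else if (auc >= 0.8) "good_to_excellent"
  else if (auc >= 0.7) "acceptable"
  else "poor"
}

#' Export ROC points as delimited text
#'
#' @param roc A [roc_curve()] result.
#' @param path Output path; two columns `fpr`, `tpr`.
#' @export
write_roc_points <- function(roc, path) {
  stopifnot(inherits(roc, "possum_roc"))
  utils::write.csv(roc$points, path, row.names = FALSE)
  invisible(path)
}
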