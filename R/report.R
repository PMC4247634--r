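# End-to-end validation: eligibility filter -> scoring -> discrimination ->
# calibration under both banding schemes -> report.

#' Run the full external-validation pipeline
#'
#' Applies the eligibility rules, scores the cohort under the model,
#' computes ROC discrimination and calibration tables under both the
#' equal-width and equal-expected-deaths banding schemes, and bundles
#' everything (with the overall O:E ratio and poor-fit / poor-discrimination
#' flags) into a deterministic report object.
#'
#' @param chrt A [cohort()] or a path to a cohort file.
#' @param model A [risk_model()] (default [possum_model()]).
#' @param k Number of risk bands (default 10).
#' @param level Confidence level (default 0.95).
#' @param df Degrees-of-freedom convention for [hl_test()]
#'   (default `"fitted"`, the audit-report convention).
#' @return An object of class \code{validation_report}.
#' @export
run_validation <- function(chrt, model = possum_model(), k = 10,
                           level = 0.95, df = "fitted") {
  if (is.character(chrt)) chrt <- read_cohort(chrt)
  stopifnot(inherits(chrt, "cohort"), inherits(model, "risk_model"))
  elig <- apply_eligibility(chrt)
  if (is.null(elig$eligible))
    stop_stat("no eligible episodes after filtering")
  ch <- elig$eligible
  pairs <- score_cohort(model, ch)
  roc <- roc_curve(pairs$risk, pairs$outcome)
  cal_w <- calibration_table(model, ch, "equal_width", k, level, df)
  cal_e <- calibration_table(model, ch, "equal_expected", k, level, df)
  structure(list(
    model = model,
    provenance = attr(ch, "provenance"),
    exclusions = elig$exclusions,
    discrimination = roc,
    calibration = list(equal_width = cal_w, equal_expected = cal_e),
    overall = cal_w$overall,
    flags = list(
      poor_fit = cal_w$hl$poor_fit,
      poor_discrimination = roc$auc < 0.7),
    config = list(k = k, level = level, df = df,
                  oe_ci_method = "exact Poisson (Garwood), expected fixed",
                  auc_se_method = roc$se_method),
    version = as.character(utils::packageVersion("possumval")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("External validation of %s on %s\n", x$model$name, x$provenance))
  cat(sprintf("  episodes: %d eligible (%d incomplete, %d indirect excluded)\n",
              x$exclusions$eligible, x$exclusions$incomplete,
              x$exclusions$indirect))
  cat(sprintf("  discrimination: AUC = %.3f +/- %.3f SE (%s)\n",
              x$discrimination$auc, x$discrimination$auc_se,
              interpret_auc(x$discrimination$auc)))
  ov <- x$overall
  cat(sprintf("  overall O:E = %.2f (%.2f - %.2f); observed %d, expected %.2f\n",
              ov$oe_ratio, ov$oe_low, ov$oe_high, ov$observed_deaths,
              ov$expected_deaths))
  hl <- x$calibration$equal_width$hl
  cat(sprintf("  HL (deciles of risk): chi-square = %.2f, df = %d, p %s%s\n",
              hl$statistic, hl$df,
              if (hl$p_value < 1e-4) "< 0.0001" else sprintf("= %.2g", hl$p_value),
              if (x$flags$poor_fit) " [poor fit]" else ""))
  invisible(x)
}

#' Write a validation report to disk
#'
#' Emits `report.json` (full unrounded numbers), `calibration.md` (tables
#' rendered to two decimals under both banding schemes) and
#' `roc_points.csv` in the output directory.
#'
#' @param report A [run_validation()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    model = unclass(report$model),
    provenance = report$provenance,
    exclusions = report$exclusions,
    discrimination = list(auc = report$discrimination$auc,
                          auc_se = report$discrimination$auc_se,
                          se_method = report$discrimination$se_method,
                          interpretation = interpret_auc(report$discrimination$auc)),
    calibration = lapply(report$calibration, function(ct) list(
      scheme = ct$scheme,
      bands = ct$bands,
      statistic = ct$hl$statistic,
      df = ct$hl$df,
      p = ct$hl$p_value)),
    overall = report$overall,
    flags = report$flags,
    config = report$config,
    version = report$version,
    timestamp = report$timestamp)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  md <- c(render_calibration_md(report$calibration$equal_width), "",
          render_calibration_md(report$calibration$equal_expected))
  writeLines(md, file.path(dir, "calibration.md"))
  write_roc_points(report$discrimination, file.path(dir, "roc_points.csv"))
  invisible(dir)
}
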