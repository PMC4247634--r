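# A cohort is a data.frame of patient episodes (one row per post-operative
# admission) carrying a provenance label.  Required columns:
#   ps, os           integer scores
#   urgency          "elective" / "non_elective"
#   specialty        general_surgery / urology / gynaecology / other
#   died_30d         0/1 outcome (death by post-operative day 30)
#   directly_admitted, data_complete   eligibility flags (logical or 0/1)

COHORT_COLUMNS <- c("ps", "os", "urgency", "specialty", "died_30d",
                    "directly_admitted", "data_complete")

SPECIALTIES <- c("general_surgery", "urology", "gynaecology", "other")

#' Construct a patient-episode cohort
#'
#' Bundles a data frame of patient episodes with a provenance label and
#' validates it: score bounds, binary outcome, recognised urgency and
#' specialty levels, logical eligibility flags.
#'
#' @param episodes Data frame with columns `ps`, `os`, `urgency`,
#'   `specialty`, `died_30d`, `directly_admitted`, `data_complete`.
#'   Extra columns are preserved but ignored by the toolkit.
#' @param provenance Character label recorded in reports.
#' @param strict Error (default) or warn on out-of-bounds scores.
#' @return A data frame of class \code{cohort}.
#' @export
cohort <- function(episodes, provenance = "unspecified", strict = TRUE) {
  stopifnot(is.data.frame(episodes))
  missing_cols <- setdiff(COHORT_COLUMNS, names(episodes))
  if (length(missing_cols))
    stop_schema("cohort is missing required column(s): ",
                paste(missing_cols, collapse = ", "))
  if (nrow(episodes) == 0L)
    stop("cohort must contain at least one episode", call. = FALSE)
  episodes <- as.data.frame(episodes)

  check_scores(episodes$ps, episodes$os, strict = strict)
  episodes$ps <- as.integer(episodes$ps)
  episodes$os <- as.integer(episodes$os)
  episodes$urgency <- normalize_urgency(episodes$urgency)
  sp <- as.character(episodes$specialty)
  if (!all(sp %in% SPECIALTIES))
    stop("unrecognised specialty value(s): ",
         paste(setdiff(unique(sp), SPECIALTIES), collapse = ", "),
         call. = FALSE)
  episodes$specialty <- sp
  y <- episodes$died_30d
  if (!all(y %in% c(0, 1)))
    stop("died_30d must be 0 or 1", call. = FALSE)
  episodes$died_30d <- as.integer(y)
  for (fl in c("directly_admitted", "data_complete")) {
    v <- episodes[[fl]]
    if (!all(v %in% c(0, 1, TRUE, FALSE)))
      stop(sprintf("'%s' must be logical or 0/1", fl), call. = FALSE)
    episodes[[fl]] <- as.logical(v)
  }
  structure(episodes, provenance = as.character(provenance),
            class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d episodes, %d deaths (%.2f%%) [%s]\n",
              nrow(x), sum(x$died_30d), 100 * mean(x$died_30d),
              attr(x, "provenance")))
  invisible(x)
}

#' Apply the cohort eligibility rules
#'
#' Removes episodes with incomplete data or that were not admitted directly
#' to the unit after surgery, the standard exclusions for a level-1-care
#' audit. An episode failing both rules is counted once, under
#' insufficient-data, so per-reason counts sum to the number excluded.
#'
#' @param raw A [cohort()].
#' @return A list with elements `eligible` (the filtered cohort, or `NULL`
#'   when nothing survives) and `exclusions`, a named list with counts
#'   `incomplete`, `indirect`, `eligible` and `total`.
#' @export
apply_eligibility <- function(raw) {
  stopifnot(inherits(raw, "cohort"))
  incomplete <- !raw$data_complete
  indirect <- !raw$directly_admitted & !incomplete  # precedence: incomplete first
  keep <- !incomplete & !indirect
  report <- list(incomplete = sum(incomplete), indirect = sum(indirect),
                 eligible = sum(keep), total = nrow(raw))
  eligible <- NULL
  if (any(keep)) {
    eligible <- raw[keep, , drop = FALSE]
    attr(eligible, "provenance") <-
      paste0(attr(raw, "provenance"), " (eligible)")
    class(eligible) <- c("cohort", "data.frame")
  } else {
    warning("no episodes remain after eligibility filtering", call. = FALSE)
  }
  list(eligible = eligible, exclusions = report)
}

#' Score every episode of a cohort under a risk model
#'
#' @param model A [risk_model()].
#' @param chrt A [cohort()]; episode order is preserved.
#' @return A data frame with columns `risk` (predicted mortality) and
#'   `outcome` (observed 30-day death), one row per episode. The column sum
#'   of `risk` is the model's expected death count for the cohort.
#' @export
score_cohort <- function(model, chrt) {
  stopifnot(inherits(model, "risk_model"), inherits(chrt, "cohort"))
  if (nrow(chrt) == 0L) stop("cannot score an empty cohort", call. = FALSE)
  data.frame(risk = predicted_risk(model, chrt$ps, chrt$os, chrt$urgency),
             outcome = chrt$died_30d)
}

# condition helpers: schema errors (malformed input) vs statistical errors
# (valid input the method cannot analyse) get distinct classes so callers
# (and the command-line wrapper) can map them to distinct exit codes.
stop_schema <- function(...) {
  stop(structure(class = c("possumval_schema_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
stop_stat <- function(...) {
  stop(structure(class = c("possumval_stat_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
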