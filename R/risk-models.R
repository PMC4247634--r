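# Linear-logistic mortality models of the POSSUM family.
#
# A risk model is ln[R/(1-R)] = intercept + coef_ps*PS + coef_os*OS +
# coef_nonelective*NE, where PS is the physiological score (sum of 12 factor
# grades, each 1/2/4/8), OS the operative severity score (6 factors) and NE an
# indicator for non-elective (emergency) surgery.

# arithmetic bounds implied by 12 and 6 factors graded 1/2/4/8
PS_MIN <- 12L
PS_MAX <- 96L
OS_MIN <- 6L
OS_MAX <- 48L

#' Construct a linear-logistic surgical mortality risk model
#'
#' A risk model maps an integer physiological score (PS) and operative
#' severity score (OS), plus optionally the urgency of surgery, to a
#' predicted 30-day mortality risk through
#' \deqn{\mathrm{ln}\frac{R}{1-R} = a + b_{PS} PS + b_{OS} OS + b_{NE} NE,}
#' where \eqn{NE = 1} for non-elective (emergency) surgery and 0 otherwise.
#'
#' @param name Model label used in reports.
#' @param intercept Intercept \eqn{a} on the log-odds scale.
#' @param coef_ps Log-odds increment per PS point.
#' @param coef_os Log-odds increment per OS point.
#' @param coef_nonelective Log-odds increment for non-elective surgery;
#'   0 (the default) for models without an urgency term.
#' @return An object of class \code{risk_model}.
#' @seealso [possum_model()], [pposum_model()], [sposum_model()],
#'   [predicted_risk()]
#' @examples
#' m <- possum_model()
#' predicted_risk(m, ps = 20, os = 14)
#' @export
risk_model <- function(name, intercept, coef_ps, coef_os, coef_nonelective = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  for (arg in c("intercept", "coef_ps", "coef_os", "coef_nonelective")) {
    v <- get(arg)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", arg), call. = FALSE)
  }
  structure(
    list(name = name, intercept = as.numeric(intercept),
         coef_ps = as.numeric(coef_ps), coef_os = as.numeric(coef_os),
         coef_nonelective = as.numeric(coef_nonelective)),
    class = "risk_model")
}

#' Predefined POSSUM-family models
#'
#' `possum_model()` is the original Copeland POSSUM mortality equation,
#' `pposum_model()` the Portsmouth refinement, and `sposum_model()` the
#' level-1-care recalibration that adds an urgency-of-surgery term:
#' \itemize{
#'   \item POSSUM: \eqn{-7.04 + 0.13\,PS + 0.16\,OS}
#'   \item P-POSSUM: \eqn{-9.065 + 0.1692\,PS + 0.155\,OS}
#'   \item S-POSSUM: \eqn{-6.505 + 0.144\,PS + 0.03\,OS + 1.057\,NE}
#' }
#'
#' @return A \code{risk_model}.
#' @rdname predefined_models
#' @export
possum_model <- function() risk_model("POSSUM", -7.04, 0.13, 0.16)

#' @rdname predefined_models
#' @export
pposum_model <- function() risk_model("P-POSSUM", -9.065, 0.1692, 0.155)

#' @rdname predefined_models
#' @export
sposum_model <- function() risk_model("S-POSSUM", -6.505, 0.144, 0.03, 1.057)

#' @export
print.risk_model <- function(x, ...) {
  ne <- if (x$coef_nonelective != 0)
    sprintf(" %+g x NE", x$coef_nonelective) else ""
  cat(sprintf("<risk_model> %s\n  ln[R/(1-R)] = %g %+g x PS %+g x OS%s\n",
              x$name, x$intercept, x$coef_ps, x$coef_os, ne))
  invisible(x)
}

# Validate integer scores against the arithmetic bounds.  With strict = TRUE a
# violation is an error naming the offending field; otherwise a warning (for
# research inputs scored under variant conventions).
check_scores <- function(ps, os, strict = TRUE) {
  signal <- if (strict) stop else warning
  bad_ps <- which(!is.finite(ps) | ps < PS_MIN | ps > PS_MAX | ps != round(ps))
  if (length(bad_ps))
    signal(sprintf(
      "physiological_score out of bounds [%d, %d] at position(s) %s",
      PS_MIN, PS_MAX, paste(utils::head(bad_ps, 5L), collapse = ", ")),
      call. = FALSE)
  bad_os <- which(!is.finite(os) | os < OS_MIN | os > OS_MAX | os != round(os))
  if (length(bad_os))
    signal(sprintf(
      "operative_score out of bounds [%d, %d] at position(s) %s",
      OS_MIN, OS_MAX, paste(utils::head(bad_os, 5L), collapse = ", ")),
      call. = FALSE)
  invisible(TRUE)
}

#' Predicted mortality risk for given scores
#'
#' Evaluates the model's logistic equation at the given physiological and
#' operative scores. Vectorised over `ps`, `os` and `urgency`; the result is
#' kept at full precision (rounding, if any, is a presentation concern).
#'
#' @param model A [risk_model()].
#' @param ps Integer physiological score(s), 12--96.
#' @param os Integer operative severity score(s), 6--48.
#' @param urgency `"elective"` or `"non_elective"` (synonym `"emergency"`);
#'   only consulted when the model carries an urgency term, and treated as
#'   elective when missing.
#' @param strict Error (default) or merely warn on out-of-bounds scores.
#' @return Numeric vector of risks, strictly inside (0, 1).
#' @examples
#' predicted_risk(possum_model(), 12, 6)        # lowest possible risk
#' predicted_risk(sposum_model(), 20, 10, "non_elective")
#' @export
predicted_risk <- function(model, ps, os, urgency = NULL, strict = TRUE) {
  stopifnot(inherits(model, "risk_model"))
  check_scores(ps, os, strict = strict)
  ne <- 0
  if (model$coef_nonelective != 0) {
    if (is.null(urgency)) {
      ne <- 0  # treated as elective when absent
    } else {
      ne <- as.numeric(normalize_urgency(urgency) == "non_elective")
    }
  }
  eta <- model$intercept + model$coef_ps * ps + model$coef_os * os +
    model$coef_nonelective * ne
  stats::plogis(eta)
}

# map urgency spellings onto {elective, non_elective}
normalize_urgency <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("elective", "0", "e"), "elective",
         ifelse(x %in% c("non_elective", "non-elective", "nonelective",
                         "emergency", "ne", "1"), "non_elective", NA))
  if (anyNA(out))
    stop("unrecognised urgency value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Serialize / deserialize a risk model as JSON
#'
#' @param model A [risk_model()].
#' @param path File path.
#' @return `read_model_json` returns a [risk_model()]; `write_model_json`
#'   returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_model(x$name, x$intercept, x$coef_ps, x$coef_os,
             if (is.null(x$coef_nonelective)) 0 else x$coef_nonelective)
}
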