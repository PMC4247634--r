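# Logistic recalibration: Newton-Raphson maximum likelihood on the binomial
# log-likelihood, Wald inference, and the urgency-augmented refit that
# produces an S-POSSUM-style model from a cohort.

#' Fit a logistic regression by Newton-Raphson
#'
#' Maximum-likelihood logistic regression written for auditability:
#' Newton-Raphson on the binomial log-likelihood with step-halving (so the
#' log-likelihood never decreases), convergence when the score (gradient)
#' max-norm falls below `tol`, and standard errors from the inverse
#' observed information at the optimum. Diverging
#' coefficients (max |b| > 30) raise a separation error rather than
#' returning a silently unstable fit.
#'
#' @param design Numeric matrix of predictors with column names, one row per
#'   observation. An intercept column is added unless `intercept = FALSE`.
#' @param outcomes Binary 0/1 response.
#' @param intercept Add an intercept column (default TRUE).
#' @param tol Convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 50).
#' @return An object of class \code{logistic_fit}: list with `coefficients`
#'   (named vector), `se`, `vcov`, `log_likelihood`, `iterations`,
#'   `converged`, `n`, `fitted` (in-sample probabilities).
#' @examples
#' # intercept-only: MLE is the logit of the observed proportion
#' y <- rep(c(1, 0), c(25, 75))
#' fit_logistic(matrix(nrow = 100, ncol = 0), y)$coefficients  # ~ -1.0986
#' @export
fit_logistic <- function(design, outcomes, intercept = TRUE,
                         tol = 1e-8, max_iter = 50L) {
  x <- as.matrix(design)
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(outcomes)
  if (!all(y %in% c(0, 1))) stop("outcomes must be binary 0/1", call. = FALSE)
  if (nrow(x) > 0 && nrow(x) != length(y))
    stop("design and outcomes must have matching rows", call. = FALSE)
  if (intercept) x <- cbind(`(Intercept)` = 1, x)
  n <- length(y)
  p <- ncol(x)
  if (p == 0L) stop("design has no columns and intercept = FALSE", call. = FALSE)
  if (n <= p) stop("more parameters than observations", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop_stat("outcomes contain a single class; logistic fit is undefined")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 & colnames(x) != "(Intercept)"))
    stop("constant non-intercept column in design: ",
         paste(colnames(x)[sds == 0 & colnames(x) != "(Intercept)"],
               collapse = ", "), call. = FALSE)

  loglik <- function(b) {
    eta <- drop(x %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  b <- numeric(p)
  ll <- loglik(b)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(drop(x %*% b))
    grad <- drop(crossprod(x, y - mu))
    w <- mu * (1 - mu)
    info <- crossprod(x, x * w)
    step <- tryCatch(solve(info, grad), error = function(e)
      stop_stat("singular information matrix at iteration ", iter))
    # step-halving: never let the log-likelihood decrease
    lambda <- 1
    repeat {
      b_new <- b + lambda * step
      ll_new <- loglik(b_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10)
        stop_stat("step-halving failed: log-likelihood cannot be improved")
    }
    if (max(abs(b_new)) > 30)
      stop_stat("coefficients diverging (max |b| > 30): ",
                "data are (quasi-)separated")
    delta_ll <- ll_new - ll
    b <- b_new
    ll <- ll_new
    trace <- c(trace, ll)
    mu <- stats::plogis(drop(x %*% b))
    grad <- drop(crossprod(x, y - mu))
    # primary criterion is the score max-norm; the log-likelihood change
    # alone can stop ~1e-4 short of the optimum in the coefficients
    if (max(abs(grad)) < tol || abs(delta_ll) < tol * 1e-4) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop_stat("Newton-Raphson did not converge in ", max_iter,
              " iterations; log-likelihood trace: ",
              paste(sprintf("%.6f", trace), collapse = ", "))
  mu <- stats::plogis(drop(x %*% b))
  info <- crossprod(x, x * (mu * (1 - mu)))
  vc <- solve(info)
  se <- sqrt(diag(vc))
  names(b) <- names(se) <- colnames(x)
  structure(list(coefficients = b, se = se, vcov = vc, log_likelihood = ll,
                 iterations = iter, converged = converged, n = n,
                 fitted = mu),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, logLik = %.3f, %d iterations\n",
              x$n, x$log_likelihood, x$iterations))
  print(coefficient_table(x))
  invisible(x)
}

#' Wald coefficient table (odds ratios and confidence intervals)
#'
#' One row per model term: log-odds estimate B, its standard error,
#' two-sided Wald p-value, the odds ratio exp(B) and its Wald interval
#' exp(B +/- z*SE). The intercept row is placed last, the layout used in
#' clinical reports.
#'
#' @param fit A converged [fit_logistic()] result.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `term`, `b`, `se`, `p`, `odds_ratio`,
#'   `or_ci_low`, `or_ci_high`.
#' @export
coefficient_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"), fit$converged)
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  se <- fit$se
  tab <- data.frame(term = names(b), b = unname(b), se = unname(se),
                    p = 2 * stats::pnorm(-abs(b / se)),
                    odds_ratio = exp(unname(b)),
                    or_ci_low = exp(unname(b) - z * unname(se)),
                    or_ci_high = exp(unname(b) + z * unname(se)))
  # intercept last
  ic <- tab$term == "(Intercept)"
  rbind(tab[!ic, , drop = FALSE], tab[ic, , drop = FALSE])
}

#' Recalibrate a POSSUM-style mortality model on a cohort
#'
#' Fits 30-day mortality on physiological score, operative score and an
#' urgency-of-surgery indicator (NE = 1 for non-elective surgery by default)
#' by maximum likelihood, packages the fit as a new [risk_model()], and runs
#' a Hosmer-Lemeshow test of the refit on the same cohort using
#' equal-expected-deaths bands. Because the maximum-likelihood score
#' equations force the fitted expected deaths to equal the observed deaths,
#' the refit is always calibrated-in-the-large on its training data.
#'
#' @param chrt An eligibility-filtered [cohort()] containing both outcome
#'   classes.
#' @param name Name for the derived model.
#' @param reverse_urgency If TRUE, code the indicator as 1 = elective
#'   instead (for replicating reports that reverse-code the category; the
#'   resulting model is converted back to the NE = non-elective convention).
#' @param k Bands for the refit's Hosmer-Lemeshow test (default 10).
#' @return A list with `model` (the recalibrated [risk_model()]), `fit`
#'   (the [fit_logistic()] result), `coefficients`
#'   (the [coefficient_table()]), and `hl` (the refit's [hl_test()]).
#' @export
derive_recalibrated_model <- function(chrt, name = "recalibrated",
                                      reverse_urgency = FALSE, k = 10) {
  stopifnot(inherits(chrt, "cohort"))
  ne <- as.numeric(chrt$urgency == "non_elective")
  ind <- if (reverse_urgency) 1 - ne else ne
  design <- cbind(PScore = chrt$ps, OScore = chrt$os,
                  urgency = ind)
  colnames(design)[3] <- if (reverse_urgency) "Elective" else "Emergency"
  fit <- fit_logistic(design, chrt$died_30d)
  b <- fit$coefficients
  u <- unname(b[4])
  # normalise to the NE = non-elective convention for the risk model
  model <- if (reverse_urgency)
    risk_model(name, unname(b["(Intercept)"]) + u, unname(b["PScore"]),
               unname(b["OScore"]), -u)
  else
    risk_model(name, unname(b["(Intercept)"]), unname(b["PScore"]),
               unname(b["OScore"]), u)
  pairs <- score_cohort(model, chrt)
  hl <- hl_test(band_equal_expected(pairs, k), df = "fitted")
  list(model = model, fit = fit, coefficients = coefficient_table(fit),
       hl = hl)
}

#' Write a coefficient table as delimited text
#'
#' @param coefficients A [coefficient_table()] data frame.
#' @param path Output path (CSV).
#' @export
write_coefficients <- function(coefficients, path) {
  utils::write.csv(coefficients, path, row.names = FALSE)
  invisible(path)
}
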