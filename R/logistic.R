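# Maximum-likelihood logistic regression by iteratively reweighted least
# squares, with Wald confidence intervals and AIC, for the adjusted
# score-outcome model.

#' Fit a logistic regression by IRLS
#'
#' Maximum-likelihood fit of `logit P(y = 1) = X b` via iteratively
#' reweighted least squares. Convergence is declared when the largest
#' absolute coefficient change falls below `tol` (default 1e-8), with at most
#' `max_iter` iterations. Standard errors come from the inverse Fisher
#' information at the optimum; 95% Wald intervals for odds ratios are
#' `exp(b +/- 1.959964 * SE)`. Complete or quasi-complete separation shows up
#' as diverging coefficients and is flagged as a non-converged fit rather
#' than an error.
#'
#' @param design Numeric matrix or data frame of predictors (no intercept
#'   column; one is added).
#' @param outcome Binary 0/1 vector with both classes present.
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @return A `logistic_fit`: coefficients, `se`, `or` with `or_ci` (matrix of
#'   95% bounds), `z`, `p`, `loglik`, `aic`, `iterations`, `converged`,
#'   `n`, `df` (number of coefficients incl. intercept).
#' @export
fit_logistic <- function(design, outcome, tol = 1e-8, max_iter = 50L) {
  x <- cbind(`(Intercept)` = 1, as.matrix(design))
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  if (qr(x)$rank < ncol(x)) stop("design is rank deficient", call. = FALSE)

  b <- numeric(ncol(x))
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% b)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    b_new <- tryCatch(solve(xtw %*% x, xtw %*% z),
                      error = function(e) NULL)
    if (is.null(b_new)) { separated <- TRUE; break }
    b_new <- drop(b_new)
    delta <- max(abs(b_new - b))
    b <- b_new
    if (max(abs(b)) > 1e3) { separated <- TRUE; break }
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(x %*% b)
  mu <- stats::plogis(eta)
  # coefficients drifting towards infinite log-odds (fitted probabilities
  # numerically 0/1) indicate complete or quasi-complete separation
  if (max(abs(eta)) > 25) separated <- TRUE
  loglik <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  info <- t(x * pmax(mu * (1 - mu), 1e-12)) %*% x
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, ncol(x)))
  zcrit <- 1.959964
  zstat <- b / se
  ci <- cbind(lower = exp(b - zcrit * se), upper = exp(b + zcrit * se))
  rownames(ci) <- colnames(x)
  names(b) <- names(se) <- colnames(x)
  structure(
    list(coefficients = b, se = se, or = exp(b), or_ci = ci,
         z = zstat, p = 2 * stats::pnorm(-abs(zstat)),
         loglik = loglik, aic = -2 * loglik + 2 * ncol(x),
         iterations = iter, converged = converged && !separated,
         separated = separated, n = length(y), df = ncol(x)),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression (IRLS), n =", x$n,
      "| iterations:", x$iterations,
      "| converged:", x$converged, "\n")
  tab <- data.frame(
    coef = round(x$coefficients, 4),
    se = round(x$se, 4),
    OR = round(x$or, 2),
    CI95 = sprintf("%.2f-%.2f", x$or_ci[, "lower"], x$or_ci[, "upper"]),
    p = format_pvalue(x$p)
  )
  print(tab)
  cat("logLik:", round(x$loglik, 2), " AIC:", round(x$aic, 1), "\n")
  invisible(x)
}

#' Compare two predictive models
#'
#' Reports both branches of a nested-model comparison: (i) the
#' likelihood-ratio chi-square `2 * (llB - llA)` with degrees of freedom
#' equal to the parameter-count difference, valid when `fit_a` is nested in
#' `fit_b`; and (ii) the paired DeLong z-test for the difference of the two
#' models' AUCs computed on identical subjects. Which branch mirrors a given
#' report's "chi-square test between models" is the caller's choice; both are
#' returned side by side.
#'
#' @param fit_a,fit_b `logistic_fit` objects, `fit_a` nested in `fit_b` (for
#'   the LRT branch); pass `NULL` for either to skip that branch.
#' @param roc_a,roc_b `roc_result` objects computed on the same subjects in
#'   the same order (for the AUC branch); pass `NULL` to skip.
#' @return List with `lrt` (`statistic`, `df`, `p`) and `auc_test`
#'   (`auc_a`, `auc_b`, `difference`, `z`, `p`).
#' @export
compare_models <- function(fit_a = NULL, fit_b = NULL,
                           roc_a = NULL, roc_b = NULL) {
  out <- list(lrt = NULL, auc_test = NULL)
  if (!is.null(fit_a) && !is.null(fit_b)) {
    if (fit_b$df < fit_a$df || fit_b$n != fit_a$n) {
      stop("LRT branch requires fit_a nested in fit_b on the same data",
           call. = FALSE)
    }
    stat <- 2 * (fit_b$loglik - fit_a$loglik)
    df <- fit_b$df - fit_a$df
    if (stat < -1e-6) {
      stop("fit_b has lower likelihood than fit_a: models are not nested ",
           "or did not converge", call. = FALSE)
    }
    stat <- max(stat, 0)
    p <- if (df == 0L) NA_real_ else stats::pchisq(stat, df, lower.tail = FALSE)
    out$lrt <- list(statistic = stat, df = df, p = p)
  }
  if (!is.null(roc_a) && !is.null(roc_b)) {
    out$auc_test <- delong_paired_test(roc_a, roc_b)
  }
  out
}
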