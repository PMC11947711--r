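# ROC analysis with DeLong confidence intervals and paired AUC comparison
# for the predictive-accuracy stage of the pipeline.

#' ROC analysis of a score against a binary outcome
#'
#' Sweeps every unique score value as a threshold (test positive when
#' `score >= threshold`), computes the (sensitivity, specificity) operating
#' points, and the AUC by the trapezoidal rule over the ROC polygon — which
#' equals the tie-adjusted concordance statistic (pairs where a case outscores
#' a control, ties counted one half). The 95% CI uses the DeLong
#' structural-components variance.
#'
#' @param score Numeric vector of predictor values (higher = more at risk).
#' @param outcome Binary 0/1 vector; both classes must be present.
#' @return A `roc_result`: `thresholds` data frame (threshold, sensitivity,
#'   specificity), `auc`, `ci` (95%), `var`, and the DeLong components `v10`
#'   (cases) and `v01` (controls).
#' @export
roc_analysis <- function(score, outcome) {
  outcome <- as.integer(outcome)
  if (length(score) != length(outcome)) stop("length mismatch", call. = FALSE)
  if (anyNA(score) || anyNA(outcome)) stop("missing values", call. = FALSE)
  cases <- score[outcome == 1L]
  controls <- score[outcome == 0L]
  m <- length(cases); n <- length(controls)
  if (m == 0L || n == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }

  thr <- sort(unique(score))
  sens <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(controls < t), numeric(1))

  # DeLong structural components via midranks
  r_all <- rank(c(cases, controls))
  r_cases <- rank(cases)
  r_controls <- rank(controls)
  v10 <- (r_all[seq_len(m)] - r_cases) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_controls) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  s10 <- if (m > 1L) stats::var(v10) else 0
  s01 <- if (n > 1L) stats::var(v01) else 0
  v <- s10 / m + s01 / n
  zcrit <- 1.959964
  ci <- c(lower = max(0, auc - zcrit * sqrt(v)),
          upper = min(1, auc + zcrit * sqrt(v)))
  structure(
    list(
      thresholds = data.frame(threshold = thr, sensitivity = sens,
                              specificity = spec),
      auc = auc, ci = ci, var = v, v10 = v10, v01 = v01,
      n_cases = m, n_controls = n
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci["lower"], x$ci["upper"], x$n_cases, x$n_controls))
  invisible(x)
}

#' Trapezoidal area under the ROC polygon
#'
#' Integrates sensitivity over 1 - specificity across the operating points of
#' a [roc_analysis] result (with the (0,0) and (1,1) corners appended).
#' Provided separately so the identity with the concordance AUC can be
#' asserted.
#'
#' @param roc A `roc_result`.
#' @return The trapezoidal AUC.
#' @export
auc_trapezoid <- function(roc) {
  fpr <- c(1, 1 - roc$thresholds$specificity, 0)
  tpr <- c(1, roc$thresholds$sensitivity, 0)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Paired DeLong test for the difference of two correlated AUCs
#'
#' Both ROC results must come from the same subjects in the same order. The
#' variance of the AUC difference uses the full 2 x 2 covariance of the
#' DeLong structural components.
#'
#' @param roc_a,roc_b `roc_result` objects on identical subjects.
#' @return List with `auc_a`, `auc_b`, `difference` (b - a), `z`, `p`.
#' @export
delong_paired_test <- function(roc_a, roc_b) {
  m <- roc_a$n_cases; n <- roc_a$n_controls
  if (roc_b$n_cases != m || roc_b$n_controls != n) {
    stop("paired AUC comparison requires identical subjects", call. = FALSE)
  }
  d <- roc_b$auc - roc_a$auc
  s10 <- stats::var(roc_a$v10) + stats::var(roc_b$v10) -
    2 * stats::cov(roc_a$v10, roc_b$v10)
  s01 <- stats::var(roc_a$v01) + stats::var(roc_b$v01) -
    2 * stats::cov(roc_a$v01, roc_b$v01)
  v <- s10 / m + s01 / n
  z <- if (v <= 0) 0 else d / sqrt(v)
  list(auc_a = roc_a$auc, auc_b = roc_b$auc, difference = d,
       z = z, p = 2 * stats::pnorm(-abs(z)))
}
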