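# Inter-parameter correlation and multicollinearity diagnostics.

#' Pairwise correlation matrix of the point-scored parameters
#'
#' Computes the symmetric correlation matrix among columns of a matrix of
#' parameter point scores. The default is a midrank-based (Spearman) rank
#' correlation, appropriate for ordinal point scores; a product-moment
#' (Pearson) option is provided. A constant column has no defined
#' correlation: its off-diagonal entries are returned as `NA` rather than
#' silently zero.
#'
#' @param x Numeric matrix or data frame, one column per parameter, >= 3 rows.
#' @param method `"rank"` (default) or `"linear"`.
#' @return Symmetric unit-diagonal matrix, possibly with `NA` entries for
#'   constant columns.
#' @export
correlation_matrix <- function(x, method = c("rank", "linear")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (method == "rank") x <- apply(x, 2L, rank)
  k <- ncol(x)
  m <- diag(k)
  dimnames(m) <- list(colnames(x), colnames(x))
  sds <- apply(x, 2L, stats::sd)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (sds[i] == 0 || sds[j] == 0) {
        m[i, j] <- m[j, i] <- NA_real_
      } else {
        xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
        m[i, j] <- m[j, i] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
      }
    }
  }
  m
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, where `R^2_j` comes from the ordinary
#' least-squares regression of predictor j on all other predictors plus an
#' intercept. VIFs are a property of the predictor columns alone and do not
#' involve any outcome variable. An exactly collinear predictor gets an
#' infinite VIF, flagged with the offending predictor named, rather than an
#' exception.
#'
#' @param design Numeric matrix or data frame of predictor columns (>= 2).
#' @param cutoff Acceptability cutoff; values below it are considered
#'   acceptable (default 5).
#' @return A `vif_report`: list with `vif` (named vector), `max_vif`,
#'   `acceptable` (max < cutoff), `cutoff`, `collinear` (names of predictors
#'   with infinite VIF, if any).
#' @export
vif <- function(design, cutoff = 5) {
  x <- as.matrix(design)
  if (ncol(x) < 2L) stop("need at least 2 predictors", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor: ", paste(colnames(x)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  k <- ncol(x)
  out <- numeric(k)
  names(out) <- colnames(x)
  for (j in seq_len(k)) {
    yj <- x[, j]
    zj <- cbind(1, x[, -j, drop = FALSE])
    fit <- stats::lm.fit(zj, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  structure(
    list(vif = out, max_vif = max(out),
         acceptable = is.finite(max(out)) && max(out) < cutoff,
         cutoff = cutoff,
         collinear = names(out)[is.infinite(out)]),
    class = "vif_report"
  )
}

#' @export
print.vif_report <- function(x, ...) {
  cat("Variance inflation factors (cutoff ", x$cutoff, "):\n", sep = "")
  print(round(x$vif, 2))
  cat("max VIF:", round(x$max_vif, 2),
      if (x$acceptable) "(acceptable)\n" else "(NOT acceptable)\n")
  if (length(x$collinear)) {
    cat("exactly collinear:", paste(x$collinear, collapse = ", "), "\n")
  }
  invisible(x)
}
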