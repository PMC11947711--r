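# Contingency and rank tests for the baseline group comparisons.

#' Pearson chi-square test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` on an r x c contingency table with
#' `df = (r-1)(c-1)` and an upper-tail chi-square p-value. For 2 x 2 tables
#' the Yates continuity correction is applied by default, mirroring the
#' conventional default for clinical tables; larger tables are never
#' corrected.
#'
#' @param table Matrix of non-negative integer counts, at least 2 x 2.
#' @param correct Apply the Yates correction to 2 x 2 tables.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_test <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (any(table < 0) || sum(table) <= 0) {
    stop("counts must be non-negative with positive grand total", call. = FALSE)
  }
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0)) {
    stop("zero marginal for row band '",
         paste(which(rs == 0), collapse = ","), "'", call. = FALSE)
  }
  if (any(cs == 0)) {
    stop("zero marginal for column band '",
         paste(which(cs == 0), collapse = ","), "'", call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(table)
  dev <- abs(table - expected)
  if (correct && nrow(table) == 2L && ncol(table) == 2L) {
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midrank tie handling and a two-sided p-value
#' from the normal approximation with tie-corrected variance. U is reported
#' for the first group: the number of (x, y) pairs with `x > y` plus half the
#' ties.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `U` (for `x`), `z`, `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))               # midranks
  r1 <- sum(r[seq_len(n1)])
  U <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- (n1 * n2 / 12) * (n + 1 - tie_term)
  if (sigma2 <= 0) return(list(U = U, z = 0, p = 1))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Screening performance of the low-risk category
#'
#' Evaluates use of the low-risk band as a rule-out screen using the
#' study's printed convention: the condition of interest is the *absence*
#' of pneumonia and a *positive* screen is the low-risk category, so
#' sensitivity = P(low risk | no pneumonia) and
#' specificity = P(not low risk | pneumonia). The conventional orientation
#' (condition = pneumonia, positive = not-low-risk) has the same two numbers
#' with the labels swapped and is returned alongside, explicitly labeled.
#'
#' @param category Factor/character of risk categories (low/moderate/high).
#' @param outcome Binary vector, 1 = pneumonia.
#' @return List with `sensitivity`, `specificity` (printed convention) and
#'   `conventional` (named list, condition positive = pneumonia).
#' @export
screening_metrics <- function(category, outcome) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2L) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  low <- category == "low"
  sens <- sum(low & outcome == 0L) / sum(outcome == 0L)
  spec <- sum(!low & outcome == 1L) / sum(outcome == 1L)
  list(
    sensitivity = sens, specificity = spec,
    conventional = list(
      condition = "pneumonia", test_positive = "not low risk",
      sensitivity = spec, specificity = sens
    )
  )
}
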