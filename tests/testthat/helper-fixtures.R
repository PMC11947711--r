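# Shared fixtures built in code.

# a healthy-baseline assessment, overridable field by field
assessment <- function(...) {
  base <- list(consciousness = 0L, spo2 = 0L, suction = 0L,
               sitting_balance = 0L, fils = 10L, resp_disease = 0L,
               nutrition = 0L, saliva = 0L)
  utils::modifyList(base, list(...))
}

# a small valid cohort data frame with a deterministic mix of bands
small_cohort <- function(n = 12L, seed = 101L) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = round(runif(n, 40, 95), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    care_certified = sample(0:1, n, replace = TRUE),
    jcs = sample(0:3, n, replace = TRUE),
    spo2_band = sample(0:2, n, replace = TRUE),
    suction_band = sample(0:2, n, replace = TRUE),
    hoffer_band = sample(0:2, n, replace = TRUE),
    fils = sample(1:10, n, replace = TRUE),
    resp_dx_count = sample(0:4, n, replace = TRUE),
    nutrition_band = sample(0:2, n, replace = TRUE),
    saliva_band = sample(0:2, n, replace = TRUE),
    pneumonia = sample(0:1, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# published risk-category x pneumonia counts (rows low/moderate/high,
# columns without/with)
risk_table_counts <- function() {
  matrix(c(283, 222, 76, 2, 13, 33), nrow = 3,
         dimnames = list(c("low", "moderate", "high"), c("without", "with")))
}

# O(n^2) concordance oracle: P(case > control) + 0.5 P(tie)
concordance_oracle <- function(score, outcome) {
  x <- score[outcome == 1]
  y <- score[outcome == 0]
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s / (length(x) * length(y))
}

# O(n^2) Mann-Whitney oracle: pairwise wins of x over y plus half-ties
u_oracle <- function(x, y) {
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s
}
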