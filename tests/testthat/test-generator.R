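# Synthetic cohort generator: correlation repair, copula marginals,
# intercept calibration, end-to-end determinism.

test_that("repair_correlation leaves positive-definite input untouched", {
  id <- diag(8)
  r <- repair_correlation(id)
  expect_equal(unclass(r), id, ignore_attr = TRUE)
  expect_equal(attr(r, "max_abs_change"), 0)
  # the default latent target matrix is already positive definite
  def <- generator_config()$latent_correlation
  r2 <- repair_correlation(def)
  expect_equal(attr(r2, "max_abs_change"), 0)
  expect_gt(min(eigen(r2, symmetric = TRUE)$values), 0)
})

test_that("repair_correlation fixes an indefinite matrix and validates input", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_lt(min(eigen(bad, symmetric = TRUE)$values), 0)
  r <- repair_correlation(bad)
  expect_gte(min(eigen(r, symmetric = TRUE)$values), 1e-7)
  expect_equal(diag(r), rep(1, 3))
  expect_equal(r, t(r))
  expect_gt(attr(r, "max_abs_change"), 0)

  expect_error(repair_correlation(matrix(c(1, 1.2, 1.2, 1), 2, 2)),
               "\\[-1, 1\\]")
  ns <- diag(3); ns[1, 2] <- 0.5
  expect_error(repair_correlation(ns), "symmetric")
  nd <- matrix(0.5, 2, 2)
  expect_error(repair_correlation(nd), "unit diagonal")
})

test_that("config validation enforces marginal and prevalence invariants", {
  expect_error(generator_config(n = 0), "n must be")
  expect_error(generator_config(target_prevalence = 0), "target_prevalence")
  bad_marg <- generator_config()$marginals
  bad_marg$spo2 <- c(0.5, 0.4, 0.2)
  expect_error(generator_config(marginals = bad_marg), "sum to 1")
})

test_that("copula sampling converges to the configured marginals", {
  cfg <- generator_config(n = 50000, seed = 2024)
  bands <- sample_parameters(cfg, seed = 2024)
  for (p in coras_parameters) {
    target <- cfg$marginals[[p]]
    emp <- tabulate(bands[, p] + 1L, nbins = length(target)) / nrow(bands)
    se <- sqrt(target * (1 - target) / nrow(bands))
    expect_true(all(abs(emp - target) <= 3 * se + 1e-12), info = p)
  }
})

test_that("a degenerate marginal yields a constant column", {
  marg <- generator_config()$marginals
  marg$saliva <- c(0, 1, 0)
  cfg <- generator_config(n = 500, marginals = marg, seed = 5)
  bands <- sample_parameters(cfg, seed = 5)
  expect_true(all(bands[, "saliva"] == 1L))
})

test_that("latent correlations order the realized rank correlations", {
  cfg <- generator_config(n = 50000, seed = 99)
  bands <- sample_parameters(cfg, seed = 99)
  cm <- correlation_matrix(bands, method = "rank")
  # latent 0.65 between sitting balance and swallowing vs 0.04 SpO2-nutrition
  expect_gt(cm["sitting_balance", "fils"], 0.4)
  expect_gt(cm["sitting_balance", "fils"], cm["spo2", "nutrition"])
})

test_that("intercept calibration matches closed forms and its tolerance", {
  expect_equal(calibrate_intercept(rep(0, 100), 0.5), 0, tolerance = 1e-6)
  expect_equal(calibrate_intercept(rep(0, 100), 0.076),
               qlogis(0.076), tolerance = 1e-5)
  cfg <- generator_config(n = 5000, seed = 3)
  synth <- generate_cohort(cfg)
  lp <- cfg$outcome_slope * synth$scores$total +
    cfg$care_log_or * synth$cohort$care_certified +
    cfg$sex_log_or * as.integer(synth$cohort$sex == "M") +
    cfg$age_log_or * (synth$cohort$age - mean(synth$cohort$age))
  expect_equal(mean(plogis(synth$intercept + lp)), 0.076, tolerance = 1e-6)
  expect_error(calibrate_intercept(rep(100, 10), 0.01), "not bracketed")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- generator_config(n = 629, seed = 17)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$intercept, b$intercept)
  expect_identical(nrow(a$cohort), 629L)
  # rows pass schema validation by construction
  expect_silent(validate_cohort(a$cohort))
  d <- generate_cohort(generator_config(n = 629, seed = 18))
  expect_false(identical(a$cohort, d$cohort))
})

test_that("simulated prevalence matches its target at large n", {
  synth <- generate_cohort(generator_config(n = 20000, seed = 8))
  p <- mean(synth$cohort$pneumonia)
  se <- sqrt(0.076 * 0.924 / 20000)
  expect_lt(abs(p - 0.076), 3 * se)
})

test_that("cohort sidecar records seed, intercept, and config hash", {
  cfg <- generator_config(n = 100, seed = 12)
  synth <- generate_cohort(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(synth, csv)
  side <- jsonlite::fromJSON(sub("\\.csv$", ".json", csv))
  expect_identical(side$seed, 12L)
  expect_equal(side$intercept, synth$intercept)
  expect_identical(side$config_hash, config_hash(cfg))
  expect_equal(nrow(read_cohort(csv)), 100L)
})
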