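# IRLS logistic regression: closed forms, reference agreement, AIC, and
# nested-model comparison.

# expand a 2x2 table (exposure x outcome) into patient-level vectors
expand_2x2 <- function(a, b, c, d) {
  # a = unexposed/no event, b = unexposed/event, c = exposed/no event,
  # d = exposed/event
  x <- c(rep(0, a + b), rep(1, c + d))
  y <- c(rep(0, a), rep(1, b), rep(0, c), rep(1, d))
  list(x = x, y = y)
}

test_that("single binary predictor reproduces the 2x2 closed form exactly", {
  for (counts in list(c(20, 10, 5, 15), c(40, 3, 17, 9))) {
    a <- counts[1]; b <- counts[2]; c <- counts[3]; d <- counts[4]
    dd <- expand_2x2(a, b, c, d)
    fit <- fit_logistic(cbind(x = dd$x), dd$y)
    expect_true(fit$converged)
    or_closed <- (a * d) / (b * c)
    se_closed <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    expect_equal(unname(fit$or["x"]), or_closed, tolerance = 1e-11)
    expect_equal(unname(fit$se["x"]), se_closed, tolerance = 1e-11)
    # Wald CI brackets the odds ratio
    expect_true(fit$or_ci["x", "lower"] < fit$or["x"] &&
                fit$or["x"] < fit$or_ci["x", "upper"])
  }
})

test_that("fit agrees with glm to high precision and AIC is consistent", {
  set.seed(44)
  n <- 300
  X <- cbind(age = rnorm(n, 70, 10), male = rbinom(n, 1, 0.5),
             score = rpois(n, 15))
  eta <- -3 + 0.06 * X[, "score"] + 0.4 * X[, "male"]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-10)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-8)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$df)
})

test_that("null data give a CI for the OR that covers 1", {
  set.seed(45)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, 0.3)
  fit <- fit_logistic(cbind(x = x), y)
  expect_true(fit$or_ci["x", "lower"] <= 1 && 1 <= fit$or_ci["x", "upper"])
})

test_that("separation is flagged as non-converged, not an error", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- x
  fit <- fit_logistic(cbind(x = x), y)
  expect_false(fit$converged)
  expect_true(fit$separated)
})

test_that("degenerate designs and outcomes are rejected", {
  expect_error(fit_logistic(cbind(x = 1:4), c(1, 1, 1, 1)), "both classes")
  expect_error(fit_logistic(cbind(a = 1:4, b = 2 * (1:4)), c(0, 1, 0, 1)),
               "rank deficient")
  expect_error(fit_logistic(cbind(x = 1:4), c(0, 1, 2, 1)), "binary")
})

test_that("AIC ordering is invariant to affine rescaling of predictors", {
  set.seed(46)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + x1))
  a1 <- fit_logistic(cbind(x1), y)$aic
  a2 <- fit_logistic(cbind(x1, x2), y)$aic
  b1 <- fit_logistic(cbind(10 * x1 + 3), y)$aic
  b2 <- fit_logistic(cbind(10 * x1 + 3, 0.1 * x2 - 7), y)$aic
  expect_equal(a1, b1, tolerance = 1e-6)
  expect_equal(a2, b2, tolerance = 1e-6)
  expect_identical(a1 < a2, b1 < b2)
})

test_that("compare_models reports both branches and validates nesting", {
  set.seed(47)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x1 + 0.8 * x2))
  fa <- fit_logistic(cbind(x1), y)
  fc <- fit_logistic(cbind(x1, x2), y)
  ra <- roc_analysis(drop(cbind(1, x1) %*% fa$coefficients), y)
  rc <- roc_analysis(drop(cbind(1, x1, x2) %*% fc$coefficients), y)
  cmp <- compare_models(fa, fc, ra, rc)
  expect_equal(cmp$lrt$statistic, 2 * (fc$loglik - fa$loglik))
  expect_identical(cmp$lrt$df, 1L)
  ref <- anova(glm(y ~ x1, family = binomial()),
               glm(y ~ x1 + x2, family = binomial()), test = "LRT")
  expect_equal(cmp$lrt$statistic, ref$Deviance[2], tolerance = 1e-8)
  expect_equal(cmp$lrt$p, ref$`Pr(>Chi)`[2], tolerance = 1e-8)
  # identical models: zero statistic, zero AUC difference
  same <- compare_models(fc, fc, rc, rc)
  expect_equal(same$lrt$statistic, 0)
  expect_equal(same$auc_test$difference, 0)
  # reversed nesting is refused
  expect_error(compare_models(fc, fa), "nested")
})
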