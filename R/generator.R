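# Gaussian-copula synthetic cohort generator.
#
# Emulates the structure of the 629-patient validation cohort: per-parameter
# ordinal marginals, a latent inter-parameter correlation structure, covariate
# marginals, and a logistic outcome model whose intercept is calibrated so
# the marginal pneumonia prevalence hits its target.

# Published per-band counts for the eight parameters (univariate table,
# without + with pneumonia). The saliva column as printed sums to 512 rather
# than the cohort's 629; the counts are used as relative frequencies.
.default_marginal_counts <- list(
  consciousness   = c(295, 276, 52, 6),
  spo2            = c(580, 35, 14),
  suction         = c(553, 61, 15),
  sitting_balance = c(282, 208, 139),
  fils            = c(231, 277, 21, 100),
  resp_disease    = c(506, 104, 17, 2),
  nutrition       = c(333, 144, 152),
  saliva          = c(17, 430, 65)
)

# Published pairwise correlations among the eight point-scored parameters
# (lower triangle), used as the latent Gaussian correlation targets.
.default_correlation <- local({
  m <- diag(8)
  lower <- c(
    0.23,
    0.48, 0.23,
    0.58, 0.23, 0.45,
    0.57, 0.18, 0.64, 0.65,
    0.11, 0.27, 0.30, 0.18, 0.26,
    0.40, 0.04, 0.31, 0.40, 0.48, 0.07,
    0.35, 0.09, 0.26, 0.39, 0.45, 0.08, 0.33
  )
  # `lower` lists the lower triangle row by row, which is the upper triangle
  # in R's column-major order
  m[upper.tri(m)] <- lower
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  dimnames(m) <- list(names(.default_marginal_counts),
                      names(.default_marginal_counts))
  m
})

#' Configuration for the synthetic-cohort generator
#'
#' Defaults reproduce the validation study's conditions: a 629-patient stroke
#' cohort, per-parameter band frequencies from the published univariate
#' table, the published 8 x 8 inter-parameter correlations as latent Gaussian
#' targets, an outcome model with odds ratios 1.06 per CoRAS point, 2.19 for
#' pre-stroke care certification, 1.73 for male sex and 1.00 per year of age,
#' and an intercept calibrated to 7.6% pneumonia prevalence.
#'
#' @param n Cohort size.
#' @param marginals Named list of per-band probability vectors (one per
#'   parameter, in severity order); each must sum to 1.
#' @param latent_correlation 8 x 8 symmetric unit-diagonal matrix of target
#'   latent correlations; repaired to positive definite if needed.
#' @param outcome_slope Log odds per CoRAS point (default `log(1.06)`).
#' @param care_log_or,sex_log_or,age_log_or Log odds for care certification,
#'   male sex, and per year of age (centered); defaults `log(2.19)`,
#'   `log(1.73)`, `log(1.00)`.
#' @param target_prevalence Marginal outcome probability (default 0.076).
#' @param age_mean,age_sd,age_range Truncated-normal age model in years;
#'   defaults approximate median 74 with interquartile range 64-82.
#' @param p_male,p_care Covariate marginals (defaults 337/629 and 172/629).
#' @param seed Integer seed for the generator's single pseudo-random stream.
#' @return A validated `generator_config` object (a named list).
#' @export
generator_config <- function(n = 629,
                             marginals = NULL,
                             latent_correlation = NULL,
                             outcome_slope = log(1.06),
                             care_log_or = log(2.19),
                             sex_log_or = log(1.73),
                             age_log_or = log(1.00),
                             target_prevalence = 0.076,
                             age_mean = 74, age_sd = 13.3,
                             age_range = c(18, 105),
                             p_male = 337 / 629, p_care = 172 / 629,
                             seed = 20200427) {
  if (is.null(marginals)) {
    marginals <- lapply(.default_marginal_counts, function(ct) ct / sum(ct))
  }
  if (is.null(latent_correlation)) latent_correlation <- .default_correlation
  cfg <- list(
    n = as.integer(n), marginals = marginals,
    latent_correlation = latent_correlation,
    outcome_slope = outcome_slope, care_log_or = care_log_or,
    sex_log_or = sex_log_or, age_log_or = age_log_or,
    target_prevalence = target_prevalence,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    p_male = p_male, p_care = p_care, seed = as.integer(seed)
  )
  .validate_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

.validate_config <- function(cfg) {
  if (cfg$n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!setequal(names(cfg$marginals), coras_parameters)) {
    stop("marginals must be named by the eight CoRAS parameters", call. = FALSE)
  }
  for (p in coras_parameters) {
    pr <- cfg$marginals[[p]]
    if (length(pr) != length(.coras_points[[p]])) {
      stop("marginal for '", p, "' must have ", length(.coras_points[[p]]),
           " bands", call. = FALSE)
    }
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-12) {
      stop("marginal probabilities for '", p, "' must be >= 0 and sum to 1",
           call. = FALSE)
    }
  }
  if (cfg$target_prevalence <= 0 || cfg$target_prevalence >= 1) {
    stop("target_prevalence must be in (0, 1)", call. = FALSE)
  }
  .check_correlation_input(cfg$latent_correlation)
  invisible(cfg)
}

.check_correlation_input <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("correlation matrix must be square", call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-10) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(m) - 1) > 1e-10)) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  if (any(m < -1 - 1e-12 | m > 1 + 1e-12)) {
    stop("correlation entries must lie in [-1, 1]", call. = FALSE)
  }
  invisible(m)
}

#' Repair a target correlation matrix to positive definiteness
#'
#' Published pairwise correlations need not form a positive-definite matrix.
#' Eigenvalues below a floor of 1e-6 are clipped to the floor, the matrix is
#' reconstructed, and the diagonal re-normalized to 1 (a one-step
#' eigenvalue-clipping approximation to the nearest correlation matrix). An
#' already positive-definite input is returned unchanged.
#'
#' @param m Symmetric unit-diagonal matrix with entries in `[-1, 1]`.
#' @param floor Smallest admissible eigenvalue.
#' @return Positive-definite correlation matrix with attribute
#'   `max_abs_change`, the largest absolute entry change the repair made.
#' @export
repair_correlation <- function(m, floor = 1e-6) {
  .check_correlation_input(m)
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) > floor) {
    attr(m, "max_abs_change") <- 0
    return(m)
  }
  vals <- pmax(e$values, floor)
  r <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- dimnames(m)
  attr(r, "max_abs_change") <- max(abs(r - m))
  r
}

#' Draw correlated ordinal parameter bands via a Gaussian copula
#'
#' Draws a latent multivariate normal vector with the (repaired) target
#' correlation matrix and cuts each coordinate at the standard-normal
#' quantiles implied by that parameter's marginal band probabilities, so
#' empirical band frequencies converge to the configured marginals while
#' preserving a monotone dependence structure.
#'
#' @param config A [generator_config].
#' @param n Number of rows to draw (defaults to `config$n`).
#' @param seed Optional seed; when `NULL` the current RNG stream is used (as
#'   inside [generate_cohort]).
#' @return Integer matrix, `n` x 8, of 0-based band indices per parameter.
#' @export
sample_parameters <- function(config, n = config$n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- repair_correlation(config$latent_correlation)
  z <- matrix(stats::rnorm(n * 8L), nrow = n) %*% chol(r)
  bands <- matrix(0L, n, 8L, dimnames = list(NULL, coras_parameters))
  for (j in seq_along(coras_parameters)) {
    p <- coras_parameters[j]
    cuts <- stats::qnorm(cumsum(config$marginals[[p]]))
    cuts <- cuts[-length(cuts)]          # k-1 interior thresholds
    bands[, j] <- findInterval(z[, j], cuts)
  }
  bands
}

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Solves, by bisection, for the intercept `c` such that the mean of
#' `plogis(c + lp)` over the sampled cohort equals the target prevalence, to
#' within 1e-6 on the probability scale.
#'
#' @param linear_predictor Numeric vector of per-patient linear predictors
#'   excluding the intercept.
#' @param target Target mean outcome probability.
#' @return The calibrated intercept (log odds).
#' @export
calibrate_intercept <- function(linear_predictor, target) {
  if (target <= 0 || target >= 1) stop("target must be in (0,1)", call. = FALSE)
  f <- function(c) mean(stats::plogis(c + linear_predictor)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) {
    stop("intercept calibration failed: target ", target,
         " not bracketed on [-50, 50]; mean probability range [",
         signif(f(lo) + target, 3), ", ", signif(f(hi) + target, 3), "]",
         call. = FALSE)
  }
  root <- (lo + hi) / 2
  while (hi - lo > 1e-12) {
    root <- (lo + hi) / 2
    fr <- f(root)
    if (abs(fr) < 1e-9) break
    if (fr < 0) lo <- root else hi <- root
  }
  if (abs(f(root)) > 1e-6) {
    stop("intercept calibration did not reach tolerance 1e-6", call. = FALSE)
  }
  root
}

# raw FILS level drawn uniformly within a scored band; a diagnosis count of
# exactly 3 stands in for the ">= 3" band (finer resolution is unobservable)
.fils_levels_by_band <- list(8:10, 7L, 4:6, 1:3)
.resp_counts_by_band <- 0:3

#' Generate a synthetic stroke-admission cohort
#'
#' Produces a full patient-level cohort in the package's CSV schema:
#' parameter bands from the Gaussian copula, raw FILS levels and diagnosis
#' counts drawn within their bands, age/sex/care-certification from their
#' marginals, and a pneumonia indicator drawn from the logistic outcome model
#' `logit P = intercept + slope * total + care_log_or * care +
#' sex_log_or * male + age_log_or * (age - mean(age))` with the intercept
#' calibrated so the mean model probability equals the target prevalence.
#' Identical config and seed reproduce the cohort exactly.
#'
#' @param config A [generator_config].
#' @return A `synthetic_cohort`: list with `cohort` (validated data frame),
#'   `intercept` (realized calibrated intercept), `scores` (the scored
#'   cohort) and `config`.
#' @export
generate_cohort <- function(config) {
  .validate_config(config)
  n <- config$n
  set.seed(config$seed)
  # fixed draw order: latent bands, FILS level, age, sex, care, outcome
  bands <- sample_parameters(config, n = n, seed = NULL)

  fils_band <- bands[, "fils"] + 1L
  fils <- vapply(fils_band, function(b) {
    lv <- .fils_levels_by_band[[b]]
    if (length(lv) == 1L) lv else lv[sample.int(length(lv), 1L)]
  }, integer(1))
  resp_count <- .resp_counts_by_band[bands[, "resp_disease"] + 1L]

  lo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- round(stats::qnorm(stats::runif(n, lo, hi),
                            config$age_mean, config$age_sd), 1)
  male <- as.integer(stats::runif(n) < config$p_male)
  care <- as.integer(stats::runif(n) < config$p_care)

  cohort <- data.frame(
    patient_id     = sprintf("P%05d", seq_len(n)),
    age            = age,
    sex            = ifelse(male == 1L, "M", "F"),
    care_certified = care,
    jcs            = bands[, "consciousness"],
    spo2_band      = bands[, "spo2"],
    suction_band   = bands[, "suction"],
    hoffer_band    = bands[, "sitting_balance"],
    fils           = fils,
    resp_dx_count  = resp_count,
    nutrition_band = bands[, "nutrition"],
    saliva_band    = bands[, "saliva"],
    pneumonia      = 0L,
    stringsAsFactors = FALSE
  )
  scores <- score_cohort(cohort)
  lp <- config$outcome_slope * scores$total +
    config$care_log_or * care +
    config$sex_log_or * male +
    config$age_log_or * (age - mean(age))
  intercept <- calibrate_intercept(lp, config$target_prevalence)
  cohort$pneumonia <- as.integer(stats::runif(n) < stats::plogis(intercept + lp))
  cohort <- validate_cohort(cohort, context = "synthetic cohort")
  structure(
    list(cohort = cohort, intercept = intercept,
         scores = score_cohort(cohort), config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: n =", nrow(x$cohort),
      "| pneumonia prevalence =",
      sprintf("%.1f%%", 100 * mean(x$cohort$pneumonia)),
      "| calibrated intercept =", sprintf("%.4f", x$intercept), "\n")
  invisible(x)
}

#' Write a synthetic cohort with its provenance sidecar
#'
#' Writes the cohort CSV plus a JSON sidecar holding the realized intercept,
#' seed, and a hash of the configuration, so a dataset can be reproduced
#' exactly from its sidecar.
#'
#' @param x A `synthetic_cohort`.
#' @param csv_path Destination for the cohort CSV.
#' @param sidecar_path Destination for the JSON sidecar (default: `csv_path`
#'   with extension `.json`).
#' @export
write_cohort <- function(x, csv_path,
                         sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  utils::write.csv(x$cohort, csv_path, row.names = FALSE, quote = FALSE)
  side <- list(
    seed = x$config$seed,
    intercept = x$intercept,
    n = x$config$n,
    config_hash = config_hash(x$config)
  )
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
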