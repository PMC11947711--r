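# Pipeline orchestration: generate/load -> score -> validate -> render.

#' Pipeline run configuration
#'
#' Exactly one of `input` (path to a cohort CSV, or an in-memory cohort data
#' frame) or `generator` (a [generator_config]) must be supplied.
#'
#' @param input Cohort CSV path or data frame, or `NULL`.
#' @param generator A [generator_config], or `NULL`.
#' @param corr_method Correlation method for the inter-parameter matrix
#'   (`"rank"` or `"linear"`).
#' @param yates Apply the Yates continuity correction to 2 x 2 tables.
#' @param seed Seed recorded in provenance (the generator's own seed governs
#'   generation).
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, generator = NULL,
                       corr_method = c("rank", "linear"), yates = TRUE,
                       seed = NULL) {
  if (is.null(input) == is.null(generator)) {
    stop("supply exactly one of 'input' or 'generator'", call. = FALSE)
  }
  structure(list(input = input, generator = generator,
                 corr_method = match.arg(corr_method), yates = yates,
                 seed = seed),
            class = "run_config")
}

.point_columns <- function(scores) {
  as.matrix(scores[paste0(coras_parameters, "_pts")])
}

#' Run the full validation pipeline
#'
#' Executes, in order: cohort load/generation and scoring; baseline
#' comparisons (sex, age, care certification, risk category) between
#' pneumonia and non-pneumonia groups with low-risk screening metrics;
#' univariate per-parameter contingency tests; the inter-parameter
#' correlation matrix and VIFs; the four-variable adjusted logistic
#' regression (age, sex, care certification, composite score); and the
#' three-model ROC/AUC/AIC comparison. Outcome-dependent analyses require
#' both outcome classes; with a one-class outcome those sections are replaced
#' by a recorded error while scoring and the correlation/VIF section are
#' still produced.
#'
#' @param config A [run_config].
#' @return An `analysis_report` list with sections `baseline`, `univariate`,
#'   `correlation`, `vif`, `logistic`, `models`, `screening`, `scores`,
#'   `errors` and `provenance`.
#' @export
run_pipeline <- function(config) {
  synth <- NULL
  if (!is.null(config$generator)) {
    synth <- generate_cohort(config$generator)
    cohort <- synth$cohort
  } else if (is.character(config$input)) {
    cohort <- read_cohort(config$input)
  } else {
    cohort <- validate_cohort(as.data.frame(config$input))
  }
  scores <- score_cohort(cohort)
  pts <- .point_columns(scores)
  y <- cohort$pneumonia
  errors <- list()
  two_class <- length(unique(y)) == 2L

  note <- function(section, expr) {
    tryCatch(expr, error = function(e) {
      errors[[section]] <<- conditionMessage(e)
      NULL
    })
  }

  baseline <- note("baseline", {
    if (!two_class) stop("outcome has a single class; baseline comparison skipped")
    sex_tab <- table(cohort$sex, y)
    care_tab <- table(cohort$care_certified, y)
    risk_tab <- table(scores$category, y)[c("low", "moderate", "high"), , drop = FALSE]
    list(
      n = nrow(cohort),
      n_pneumonia = sum(y),
      prevalence = mean(y),
      sex = chi_square_test(sex_tab, correct = config$yates),
      age = mann_whitney(cohort$age[y == 1L], cohort$age[y == 0L]),
      age_median = c(
        without = stats::median(cohort$age[y == 0L]),
        with = stats::median(cohort$age[y == 1L])
      ),
      care = chi_square_test(care_tab, correct = config$yates),
      risk = chi_square_test(as.matrix(risk_tab), correct = FALSE),
      risk_table = as.matrix(risk_tab),
      risk_incidence = risk_tab[, "1"] / rowSums(risk_tab)
    )
  })

  screening <- note("screening", {
    if (!two_class) stop("outcome has a single class; screening skipped")
    screening_metrics(scores$category, y)
  })

  univariate <- note("univariate", {
    if (!two_class) stop("outcome has a single class; univariate tests skipped")
    lapply(stats::setNames(nm = coras_parameters), function(p) {
      tab <- table(pts[, paste0(p, "_pts")], y)
      test <- chi_square_test(as.matrix(tab), correct = config$yates)
      list(table = as.matrix(tab), statistic = test$statistic,
           df = test$df, p = test$p)
    })
  })

  corr <- correlation_matrix(pts, method = config$corr_method)
  colnames(corr) <- rownames(corr) <- coras_parameters
  vif8 <- vif(pts)

  logistic <- note("logistic", {
    if (!two_class) stop("outcome has a single class; logistic model skipped")
    design <- .adjusted_design(cohort, scores)
    list(fit = fit_logistic(design, y), vif = vif(design))
  })

  models <- note("models", {
    if (!two_class) stop("outcome has a single class; model comparison skipped")
    .model_comparison(cohort, scores, y)
  })

  structure(
    list(
      baseline = baseline, univariate = univariate, correlation = corr,
      vif = vif8, logistic = logistic, models = models,
      screening = screening, scores = scores, errors = errors,
      synthetic = if (!is.null(synth)) {
        list(intercept = synth$intercept, seed = config$generator$seed)
      },
      provenance = list(
        config_hash = config_hash(config),
        seed = if (!is.null(config$generator)) config$generator$seed else config$seed,
        n = nrow(cohort),
        corr_method = config$corr_method,
        yates = config$yates,
        package_version = as.character(utils::packageVersion("coras"))
      )
    ),
    class = "analysis_report"
  )
}

# four-variable adjusted design in reporting order: age, sex, care, score
.adjusted_design <- function(cohort, scores) {
  cbind(
    age = cohort$age,
    sex_male = as.integer(cohort$sex == "M"),
    care_certified = cohort$care_certified,
    coras = scores$total
  )
}

.model_comparison <- function(cohort, scores, y) {
  covars <- .adjusted_design(cohort, scores)[, c("age", "sex_male", "care_certified")]
  full <- .adjusted_design(cohort, scores)
  fit_a <- fit_logistic(covars, y)                    # age + sex + care
  fit_b <- fit_logistic(cbind(coras = scores$total), y)  # score alone
  fit_c <- fit_logistic(full, y)                      # all four
  roc_a <- roc_analysis(drop(cbind(1, covars) %*% fit_a$coefficients), y)
  roc_b <- roc_analysis(scores$total, y)
  roc_c <- roc_analysis(drop(cbind(1, full) %*% fit_c$coefficients), y)
  list(
    fits = list(a = fit_a, b = fit_b, c = fit_c),
    rocs = list(a = roc_a, b = roc_b, c = roc_c),
    table = data.frame(
      model = c("age + sex + care level", "CoRAS", "age + sex + care level + CoRAS"),
      auc = c(roc_a$auc, roc_b$auc, roc_c$auc),
      ci_lower = c(roc_a$ci["lower"], roc_b$ci["lower"], roc_c$ci["lower"]),
      ci_upper = c(roc_a$ci["upper"], roc_b$ci["upper"], roc_c$ci["upper"]),
      aic = c(fit_a$aic, fit_b$aic, fit_c$aic)
    ),
    # a is nested in c and b is nested in c; a vs b are not nested, so only
    # the paired-AUC branch applies there
    a_vs_c = compare_models(fit_a, fit_c, roc_a, roc_c),
    b_vs_c = compare_models(fit_b, fit_c, roc_b, roc_c),
    a_vs_b = compare_models(roc_a = roc_a, roc_b = roc_b)
  )
}

#' Replay a pre-tabulated risk-category table
#'
#' Accepts an aggregated 3 x 2 contingency table (rows low/moderate/high risk,
#' columns without/with pneumonia) — the form in which cohort results are
#' printed — and computes overall prevalence, per-category incidence, the
#' low-risk screening pair under the printed convention, and the chi-square
#' test across categories. This lets published tables be replayed directly
#' without patient-level data.
#'
#' @param counts 3 x 2 numeric matrix; rows in order low, moderate, high;
#'   columns in order without, with pneumonia.
#' @return List with `n`, `prevalence`, `incidence` (per category),
#'   `sensitivity`, `specificity`, `chi_square`.
#' @export
replay_risk_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 2L))) {
    stop("expected a 3 x 2 table (low/moderate/high x without/with)",
         call. = FALSE)
  }
  rownames(counts) <- c("low", "moderate", "high")
  colnames(counts) <- c("without", "with")
  category <- rep(rownames(counts), times = rowSums(counts))
  outcome <- unlist(lapply(rownames(counts), function(rn) {
    rep(c(0L, 1L), times = counts[rn, ])
  }))
  sm <- screening_metrics(category, outcome)
  list(
    n = sum(counts),
    prevalence = sum(counts[, "with"]) / sum(counts),
    incidence = counts[, "with"] / rowSums(counts),
    sensitivity = sm$sensitivity,
    specificity = sm$specificity,
    chi_square = chi_square_test(counts, correct = FALSE)
  )
}
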