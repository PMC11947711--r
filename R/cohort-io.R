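# Cohort CSV schema, validation, and score output.

# column -> legal range check; NULL max means unbounded above
.cohort_schema <- list(
  patient_id     = list(kind = "id"),
  age            = list(kind = "numeric", min = 0, max = 130),
  sex            = list(kind = "enum", values = c("F", "M")),
  care_certified = list(kind = "integer", min = 0L, max = 1L),
  jcs            = list(kind = "integer", min = 0L, max = 3L),
  spo2_band      = list(kind = "integer", min = 0L, max = 2L),
  suction_band   = list(kind = "integer", min = 0L, max = 2L),
  hoffer_band    = list(kind = "integer", min = 0L, max = 2L),
  fils           = list(kind = "integer", min = 1L, max = 10L),
  resp_dx_count  = list(kind = "integer", min = 0L, max = NA),
  nutrition_band = list(kind = "integer", min = 0L, max = 2L),
  saliva_band    = list(kind = "integer", min = 0L, max = 2L),
  pneumonia      = list(kind = "integer", min = 0L, max = 1L)
)

#' Read and validate a cohort CSV
#'
#' Reads a patient-level cohort table in the package's CSV schema (see the
#' README for column encodings) and validates every cell. Violations are
#' collected and reported together with their row and column so that a file
#' can be fixed in one pass; any violation aborts the read. Missing values
#' are violations — records with absent assessments are rejected, not
#' imputed.
#'
#' @param path Path to a CSV file with a single header row.
#' @return A validated `data.frame`, one row per patient.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df, context = path)
}

#' Validate an in-memory cohort table
#'
#' @param df Data frame in the cohort schema.
#' @param context Label used in error messages (e.g. the file name).
#' @return The validated data frame, invisibly coerced to canonical types.
#' @export
validate_cohort <- function(df, context = "cohort") {
  missing_cols <- setdiff(names(.cohort_schema), names(df))
  if (length(missing_cols)) {
    stop(context, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  for (col in names(.cohort_schema)) {
    spec <- .cohort_schema[[col]]
    x <- df[[col]]
    bad_na <- which(is.na(x))
    if (length(bad_na)) {
      problems <- c(problems, sprintf("row %d, column '%s': missing value",
                                      bad_na, col))
      next
    }
    if (spec$kind == "enum") {
      bad <- which(!x %in% spec$values)
      if (length(bad)) {
        problems <- c(problems, sprintf(
          "row %d, column '%s': value '%s' not in {%s}",
          bad, col, x[bad], paste(spec$values, collapse = ",")))
      }
    } else if (spec$kind %in% c("integer", "numeric")) {
      if (!is.numeric(x)) {
        problems <- c(problems, sprintf("column '%s': not numeric", col))
        next
      }
      if (spec$kind == "integer" && any(x != floor(x))) {
        bad <- which(x != floor(x))
        problems <- c(problems, sprintf(
          "row %d, column '%s': non-integer value %s", bad, col, x[bad]))
      }
      lo <- spec$min
      hi <- spec$max
      bad <- which(x < lo | (!is.na(hi) & x > hi))
      if (length(bad)) {
        problems <- c(problems, sprintf(
          "row %d, column '%s': value %s out of range [%s, %s]",
          bad, col, x[bad], lo, if (is.na(hi)) "Inf" else hi))
      }
    }
  }
  if (length(problems)) {
    stop(context, ": ", length(problems), " schema violation(s)\n  ",
         paste(utils::head(problems, 20L), collapse = "\n  "),
         if (length(problems) > 20L) "\n  ..." else "", call. = FALSE)
  }
  for (col in names(.cohort_schema)) {
    if (.cohort_schema[[col]]$kind == "integer") df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' Score a validated cohort
#'
#' Applies the CoRAS table to every patient of a cohort data frame.
#'
#' @param cohort Validated cohort data frame (see [read_cohort]).
#' @return Data frame with `patient_id`, the eight per-parameter point
#'   columns (suffixed `_pts`), `total` and `category`.
#' @export
score_cohort <- function(cohort) {
  res <- total_score(list(
    consciousness   = cohort$jcs,
    spo2            = cohort$spo2_band,
    suction         = cohort$suction_band,
    sitting_balance = cohort$hoffer_band,
    fils            = cohort$fils,
    resp_disease    = cohort$resp_dx_count,
    nutrition       = cohort$nutrition_band,
    saliva          = cohort$saliva_band
  ))
  out <- as.data.frame(res$points)
  names(out) <- paste0(names(out), "_pts")
  cbind(data.frame(patient_id = cohort$patient_id), out,
        data.frame(total = res$total, category = as.character(res$category)))
}

#' Write a scored cohort to CSV
#'
#' @param scores Output of [score_cohort].
#' @param path Destination CSV path.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
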