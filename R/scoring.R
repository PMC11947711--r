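# CoRAS scoring table and risk stratification.
#
# Eight admission parameters, each assessed by the discipline that routinely
# measures it, are mapped to integer point values that sum to at most 100.
# All arithmetic is integer; there is no floating point anywhere in scoring.

#' CoRAS parameter identifiers
#'
#' The eight parameters of the Collaborative Respiratory Assessment Score, in
#' canonical order: consciousness level (Japan Coma Scale), SpO2 band, need
#' for suctioning, sitting balance (Hoffer criteria), swallowing dysfunction
#' (Food Intake Level Scale), history of respiratory diseases, nutritional
#' status (MUST/GLIM) and saliva (OHAT-J oral-dryness item).
#'
#' @format Character vector of length 8.
#' @export
coras_parameters <- c(
  "consciousness", "spo2", "suction", "sitting_balance",
  "fils", "resp_disease", "nutrition", "saliva"
)

# Point values per band, in increasing severity order. FILS and respiratory
# disease history take raw values (level 1-10, diagnosis count >= 0) that are
# banded internally; the remaining six take band codes 0,1,2(,3).
.coras_points <- list(
  consciousness   = c(0L, 3L, 10L, 15L),  # clear / JCS I / JCS II / JCS III
  spo2            = c(0L, 5L, 10L),       # >=95% / 92-94% / <=91% or on oxygen
  suction         = c(0L, 10L, 20L),      # none / 1-7 per day / >=8 per day
  sitting_balance = c(0L, 5L, 15L),       # no hand support / hand support / unable
  fils            = c(0L, 5L, 10L, 15L),  # levels 8-10 / 7 / 4-6 / 1-3
  resp_disease    = c(0L, 5L, 8L, 10L),   # 0 / 1 / 2 / >=3 diagnoses
  nutrition       = c(0L, 5L, 10L),       # normal or overnutrition / at risk / malnourished
  saliva          = c(0L, 3L, 5L)         # healthy / changes present / pathological
)

# Band labels accepted as character input, one vector per parameter, in the
# same severity order as .coras_points.
.coras_labels <- list(
  consciousness   = c("clear", "JCS-I", "JCS-II", "JCS-III"),
  spo2            = c(">=95%", "92-94%", "<=91%-or-oxygen"),
  suction         = c("none", "1-7/day", ">=8/day"),
  sitting_balance = c("no-hand-support", "hand-support", "unable"),
  nutrition       = c("normal/overnutrition", "at-risk", "malnourished"),
  saliva          = c("healthy", "changes-present", "pathological")
)

# FILS level (1-10) -> severity band index 1-4. The printed band boundaries
# overlap at levels 8-9; the less severe band takes precedence so the ten
# levels partition cleanly: 8-10 -> 0 pts, 7 -> 5, 4-6 -> 10, 1-3 -> 15.
.fils_band <- function(level) {
  ifelse(level >= 8L, 1L, ifelse(level == 7L, 2L, ifelse(level >= 4L, 3L, 4L)))
}

# Respiratory diagnosis count -> band index 1-4 (0 / 1 / 2 / >=3).
.resp_band <- function(count) pmin(count, 3L) + 1L

#' Look up the point value for one CoRAS parameter
#'
#' Maps a raw assessment to its integer point contribution. Band-coded
#' parameters accept either an integer band code (0-based, in increasing
#' severity) or the band label; `fils` takes the raw level 1-10 and
#' `resp_disease` the raw diagnosis count.
#'
#' @param parameter One of [coras_parameters].
#' @param value Band code, band label, FILS level, or diagnosis count.
#'   Vectorized.
#' @param on_oxygen Logical, only honoured for `parameter = "spo2"`: a patient
#'   on oxygen therapy scores the worst SpO2 band regardless of the reading.
#' @return Integer vector of point values.
#' @examples
#' points_for("consciousness", "JCS-III")  # 15
#' points_for("resp_disease", 2)           # 8
#' points_for("fils", 7)                   # 5
#' @export
points_for <- function(parameter, value, on_oxygen = FALSE) {
  if (length(parameter) != 1L || !parameter %in% coras_parameters) {
    stop("unknown CoRAS parameter: ", paste(parameter, collapse = ", "),
         call. = FALSE)
  }
  pts <- .coras_points[[parameter]]
  if (parameter == "fils") {
    value <- .validate_integerish(value, "fils")
    if (any(value < 1L | value > 10L)) {
      stop("field 'fils': level must be in 1..10, got ",
           paste(value[value < 1L | value > 10L], collapse = ", "),
           call. = FALSE)
    }
    return(pts[.fils_band(value)])
  }
  if (parameter == "resp_disease") {
    value <- .validate_integerish(value, "resp_dx_count")
    if (any(value < 0L)) {
      stop("field 'resp_dx_count': count must be >= 0", call. = FALSE)
    }
    return(pts[.resp_band(value)])
  }
  band <- .coerce_band(parameter, value)
  if (parameter == "spo2" && length(on_oxygen)) {
    band[rep_len(as.logical(on_oxygen), length(band))] <- 2L
  }
  pts[band + 1L]
}

.coerce_band <- function(parameter, value) {
  nb <- length(.coras_points[[parameter]])
  if (is.character(value) || is.factor(value)) {
    idx <- match(as.character(value), .coras_labels[[parameter]])
    if (anyNA(idx)) {
      stop("field '", parameter, "': unknown band label ",
           paste(unique(value[is.na(idx)]), collapse = ", "), call. = FALSE)
    }
    return(idx - 1L)
  }
  value <- .validate_integerish(value, parameter)
  if (any(value < 0L | value >= nb)) {
    stop("field '", parameter, "': band code must be in 0..", nb - 1L,
         call. = FALSE)
  }
  value
}

.validate_integerish <- function(x, field) {
  if (anyNA(x)) stop("field '", field, "': missing value", call. = FALSE)
  if (!is.numeric(x) || any(x != floor(x))) {
    stop("field '", field, "': expected integer values", call. = FALSE)
  }
  as.integer(x)
}

#' Compute the composite CoRAS score for one or more patients
#'
#' Sums the eight per-parameter point values into the 0-100 composite score
#' and assigns the risk category. A record with any missing assessment is
#' rejected (the score was designed for, and validated on, complete data);
#' no imputation is performed.
#'
#' @param assessment A list or one-row data frame with fields
#'   `consciousness`, `spo2`, `suction`, `sitting_balance` (band codes or
#'   labels), `fils` (level 1-10), `resp_disease` (diagnosis count),
#'   `nutrition`, `saliva`, and optionally `on_oxygen`. For a multi-row data
#'   frame every row is scored.
#' @return An object of class `coras_result`: a list with `points` (named
#'   integer matrix, one row per patient), `total` (integer vector 0-100) and
#'   `category` (factor low/moderate/high).
#' @examples
#' total_score(list(consciousness = 1, spo2 = 1, suction = 1,
#'                  sitting_balance = 1, fils = 5, resp_disease = 1,
#'                  nutrition = 1, saliva = 1))$total  # 46
#' @export
total_score <- function(assessment) {
  assessment <- as.list(assessment)
  missing <- setdiff(coras_parameters, names(assessment))
  if (length(missing)) {
    stop("missing assessment field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  on_oxygen <- if (!is.null(assessment$on_oxygen)) assessment$on_oxygen else FALSE
  n <- length(assessment$consciousness)
  pts <- vapply(coras_parameters, function(p) {
    points_for(p, assessment[[p]], on_oxygen = on_oxygen)
  }, integer(n))
  pts <- matrix(as.integer(pts), ncol = 8L,
                dimnames = list(NULL, coras_parameters))
  total <- as.integer(rowSums(pts))
  structure(
    list(points = pts, total = total, category = categorize(total)),
    class = "coras_result"
  )
}

#' @export
print.coras_result <- function(x, ...) {
  n <- length(x$total)
  cat("CoRAS result:", n, if (n == 1L) "patient\n" else "patients\n")
  print(utils::head(data.frame(x$points, total = x$total,
                               category = x$category), 10L))
  if (n > 10L) cat("... (", n - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Risk category for a composite CoRAS total
#'
#' Thresholds were fixed a priori by the multidisciplinary working group:
#' totals 0-14 are low risk, 15-39 moderate risk, 40-100 high risk.
#'
#' @param total Integer vector of composite scores in 0-100.
#' @return Factor with ordered levels `low`, `moderate`, `high`.
#' @export
categorize <- function(total) {
  total <- .validate_integerish(total, "total")
  if (any(total < 0L | total > 100L)) {
    stop("total must be in 0..100", call. = FALSE)
  }
  factor(
    ifelse(total <= 14L, "low", ifelse(total <= 39L, "moderate", "high")),
    levels = c("low", "moderate", "high"), ordered = TRUE
  )
}

#' Enumerate every attainable band combination
#'
#' Expands all 4 x 3 x 3 x 3 x 4 x 4 x 3 x 3 = 15,552 combinations of scoring
#' bands and returns their totals; useful for exhaustive verification of the
#' score's range.
#'
#' @return Data frame of band point contributions with a `total` column.
#' @export
enumerate_scores <- function() {
  g <- expand.grid(.coras_points, KEEP.OUT.ATTRS = FALSE)
  g$total <- as.integer(rowSums(g))
  g
}
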