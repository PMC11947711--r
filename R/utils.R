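# Small shared helpers.

#' Hash a generator or run configuration
#'
#' Stable 32-bit FNV-1a hash of the canonical JSON serialization of a
#' configuration, used in provenance blocks and sidecar files.
#'
#' @param config Any serializable list.
#' @return Hex string of 8 characters.
#' @export
config_hash <- function(config) {
  declass <- function(x) {
    if (is.list(x) && !is.data.frame(x)) lapply(unclass(x), declass) else x
  }
  s <- jsonlite::toJSON(declass(config), auto_unbox = TRUE, digits = 15,
                        null = "null", force = TRUE)
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- .xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of a 32-bit unsigned value (stored as double) with a byte
.xor32 <- function(h, b) {
  low <- h %% 256
  h - low + bitwXor(as.integer(low), b)
}

#' Format a p-value in the reporting style of clinical tables
#'
#' Three decimals, with values below 0.001 collapsed to `"<0.001"`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}
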