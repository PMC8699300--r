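#' Reverse-complement DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @keywords internal
#' @noRd
rc_dna <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# classed validation errors so callers can distinguish failure modes
abort_schema <- function(msg) {
  rlang::abort(msg, class = "epialleler_error_schema")
}
abort_duplicate_barcode <- function(msg) {
  rlang::abort(msg, class = "epialleler_error_duplicate_barcode")
}
abort_cpg_site <- function(msg) {
  rlang::abort(msg, class = "epialleler_error_cpg_site")
}
abort_duplicate_assignment <- function(msg) {
  rlang::abort(msg, class = "epialleler_error_duplicate_assignment")
}

# character matrix (reads x positions) from a vector of equal-role strings,
# extracting only the requested 1-based positions
chars_at <- function(x, positions) {
  out <- matrix("", nrow = length(x), ncol = length(positions))
  for (k in seq_along(positions)) {
    out[, k] <- substr(x, positions[k], positions[k])
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
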