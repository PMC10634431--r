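#' Standardize a generic amino-acid sequence (e.g. an epitope)
#'
#' Trims surrounding whitespace, upper-cases, and accepts the value only if
#' every character is one of the 20 standard amino-acid one-letter codes.
#' Gaps, digits, punctuation and ambiguity letters (B, J, O, U, X, Z) are
#' rejected; rejected values return `NA` with a warning.
#'
#' @param sequences Character vector of raw sequences.
#' @param suppress_warnings Silence per-value diagnostics.
#' @return Character vector of upper-cased validated sequences, `NA` on
#'   failure.
#' @examples
#' aa_standardize("VMAPRTLIL")  # "VMAPRTLIL"
#' aa_standardize("acdefg")     # "ACDEFG"
#' @export
aa_standardize <- function(sequences, suppress_warnings = FALSE) {
  res <- aa_standardize_detail(sequences)
  emit_diagnostics(res$diagnostic, suppress = suppress_warnings)
  res$value
}

aa_standardize_detail <- function(sequences) {
  input <- as.character(sequences)
  s <- toupper(trimws(input))
  valid <- !is.na(s) & nzchar(s) &
    grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), s)
  value <- ifelse(valid, s, NA_character_)
  diagnostic <- ifelse(valid, NA_character_, sprintf(
    "Input \"%s\" was rejected as it is not a valid amino acid sequence.",
    ifelse(is.na(input), "<NA>", input)))
  data.frame(input = input, value = value, diagnostic = diagnostic,
             stringsAsFactors = FALSE)
}

#' Standardize a TR junction (CDR3) amino-acid sequence
#'
#' Applies [aa_standardize()] validation, then enforces junction framing: a
#' valid junction starts with a cysteine (C) and ends with a phenylalanine
#' (F) or tryptophan (W). Sequences already framed are returned unchanged.
#' Otherwise, with `strict = FALSE` (default) the value is repaired: a
#' sequence that does not start with C is taken to be a bare CDR3 and is
#' wrapped with a leading `"C"` and a trailing `"F"` (so `"sadaf"` becomes
#' `"CSADAFF"`), while a C-initial sequence with an invalid terminal residue
#' only gains the trailing `"F"`. The repair always appends `"F"`, never
#' `"W"`. With `strict = TRUE` unframed sequences are rejected instead.
#'
#' The empty string always fails; a single valid residue is repaired on both
#' sides in non-strict mode.
#'
#' @param sequences Character vector of raw junction sequences.
#' @param strict If `TRUE`, reject instead of repairing unframed sequences.
#' @param suppress_warnings Silence per-value diagnostics.
#' @return Character vector of standardized junctions, `NA` on failure.
#' @examples
#' junction_standardize("sadaf")                  # "CSADAFF"
#' junction_standardize("sadaf", strict = TRUE)   # NA, with a warning
#' junction_standardize("CSVNRDTGAGGYTF")         # unchanged
#' @export
junction_standardize <- function(sequences, strict = FALSE,
                                 suppress_warnings = FALSE) {
  res <- junction_standardize_detail(sequences, strict = strict)
  emit_diagnostics(res$diagnostic, suppress = suppress_warnings)
  res$value
}

junction_standardize_detail <- function(sequences, strict = FALSE) {
  aa <- aa_standardize_detail(sequences)
  value <- aa$value
  diagnostic <- ifelse(
    is.na(value),
    sprintf("Input \"%s\" was rejected as it is not a valid junction sequence.",
            ifelse(is.na(aa$input), "<NA>", aa$input)),
    NA_character_)

  ok <- !is.na(value)
  framed <- ok & grepl("^C[A-Z]*[FW]$", value) & nchar(value) >= 2L
  if (isTRUE(strict)) {
    reject <- ok & !framed
    diagnostic[reject] <- sprintf(
      "Input \"%s\" was rejected as it is not a valid junction sequence.",
      aa$input[reject])
    value[reject] <- NA_character_
  } else {
    # Unframed sequences not starting with C are taken to be bare CDR3s and
    # wrapped on both ends; C-initial sequences with an invalid terminal
    # residue only gain the terminal "F".
    fix <- ok & !framed
    wrap <- fix & !grepl("^C", value)
    value[wrap] <- paste0("C", value[wrap], "F")
    append_f <- fix & !wrap
    value[append_f] <- paste0(value[append_f], "F")
  }
  data.frame(input = aa$input, value = value, diagnostic = diagnostic,
             stringsAsFactors = FALSE)
}
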