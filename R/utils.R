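#' @keywords internal
"_PACKAGE"

# Supported species identifiers, in the string form used throughout the API.
SPECIES <- c("homosapiens", "musmusculus")

# The 20 standard amino-acid one-letter codes.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_species <- function(species) {
  if (!is.character(species) || length(species) != 1L || is.na(species) ||
      !species %in% SPECIES) {
    stop("Unknown species ", deparse(substitute(species)), ": ",
         if (is.character(species)) paste0("\"", species, "\"") else "<non-string>",
         ". Supported species are \"homosapiens\" and \"musmusculus\".",
         call. = FALSE)
  }
  species
}

# Normalize free-text species labels ("Homo sapiens", "MUS MUSCULUS") to the
# API identifiers; returns NA_character_ for unsupported labels.
normalize_species_label <- function(labels) {
  x <- tolower(gsub("[ _-]", "", trimws(as.character(labels))))
  out <- rep(NA_character_, length(x))
  out[x %in% SPECIES] <- x[x %in% SPECIES]
  out
}

# Zero-pad a numeric allele field to two digits ("1" -> "01"); non-numeric
# fields are returned upper-cased and unchanged.
pad_allele_field <- function(x) {
  num <- grepl("^[0-9]+$", x)
  x[num] <- ifelse(nchar(x[num]) < 2L, sprintf("%02d", as.integer(x[num])), x[num])
  x
}

# Emit per-value diagnostics as warnings, capped so that batch runs do not
# flood the console. Suppression is per-call or via
# options(imgtidy.suppress_warnings = TRUE).
emit_diagnostics <- function(diagnostics, suppress = FALSE, cap = 10L) {
  if (isTRUE(suppress) || isTRUE(getOption("imgtidy.suppress_warnings", FALSE))) {
    return(invisible(NULL))
  }
  diagnostics <- diagnostics[!is.na(diagnostics) & nzchar(diagnostics)]
  if (length(diagnostics) == 0L) return(invisible(NULL))
  shown <- utils::head(diagnostics, cap)
  for (d in shown) warning(d, call. = FALSE)
  extra <- length(diagnostics) - length(shown)
  if (extra > 0L) {
    warning(sprintf("... and %d further standardization diagnostics suppressed.", extra),
            call. = FALSE)
  }
  invisible(NULL)
}
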