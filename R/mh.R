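#' Standardize MH (HLA / H2) gene symbols
#'
#' Converts potentially non-standard major histocompatibility gene symbols to
#' IMGT-compliant form. Human symbols use the `HLA-` prefix; mouse genes use
#' the IMGT `MH1-`/`MH2-` names, with legacy `H2-`/`H-2` names and deprecated
#' synonyms (e.g. `CRW2`) resolved through the registry synonym table.
#'
#' Pipeline per value: trim and upper-case; if the string contains
#' whitespace, resolve the first resolvable whitespace-delimited token and
#' discard the rest (qualifiers such as `"... W167A mutant"` are dropped;
#' a string none of whose tokens resolves fails); split allele fields at
#' `"*"` and `":"`, zero-padding each numeric field to two digits and
#' discarding fields beyond the fourth with a diagnostic; resolve the root by
#' direct registry lookup, then (human) by prepending `"HLA-"`, then (mouse)
#' by rewriting `H-2`/`H2-` legacy names via the synonym table. Roots absent
#' from the registry — including non-classical MH genes such as MR1, class-
#' level labels such as `"HLA class II"` or `"HLA-DQ"`, and bare mutation
#' specifiers — fail with a warning and `NA`.
#'
#' @param symbols Character vector of raw MH gene symbols.
#' @param species `"homosapiens"` (default) or `"musmusculus"`.
#' @param precision `"allele"` keeps all allele fields, `"protein"` keeps at
#'   most the first two colon-separated fields, `"gene"` keeps none.
#' @param suppress_warnings Silence per-value diagnostics.
#' @return Character vector of standardized symbols, `NA` on failure.
#' @examples
#' mh_standardize("HLA-A*01:01:01", precision = "protein")  # "HLA-A*01:01"
#' mh_standardize("CRW2", species = "musmusculus")          # "MH1-M5"
#' mh_standardize("DQB1*06:02")                             # "HLA-DQB1*06:02"
#' @export
mh_standardize <- function(symbols, species = "homosapiens",
                           precision = c("allele", "protein", "gene"),
                           suppress_warnings = FALSE) {
  res <- mh_standardize_detail(symbols, species = species, precision = precision)
  emit_diagnostics(res$diagnostic, suppress = suppress_warnings)
  res$value
}

mh_standardize_detail <- function(symbols, species = "homosapiens",
                                  precision = c("allele", "protein", "gene")) {
  check_species(species)
  precision <- match.arg(precision)
  reg <- load_reference(species)
  out <- lapply(as.list(symbols), function(s) {
    .mh_standardize_one(s, reg, species, precision)
  })
  data.frame(
    input = as.character(symbols),
    value = vapply(out, `[[`, character(1), "value"),
    diagnostic = vapply(out, `[[`, character(1), "diagnostic"),
    stringsAsFactors = FALSE
  )
}

.mh_fail <- function(raw, species, reason, attempted = NULL) {
  raw_txt <- if (is.character(raw) && length(raw) == 1L && !is.na(raw)) raw else "<non-string>"
  msg <- sprintf("Failed to standardize \"%s\" for species %s: %s.",
                 raw_txt, species, reason)
  if (!is.null(attempted)) {
    msg <- paste0(msg, sprintf(" Attempted fix \"%s\".", attempted))
  }
  list(value = NA_character_, diagnostic = msg)
}

.mh_standardize_one <- function(raw, reg, species, precision) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    return(.mh_fail(raw, species, "input is not a string"))
  }
  s <- toupper(trimws(raw))
  if (!nzchar(s)) {
    return(.mh_fail(raw, species, "input is empty"))
  }
  tokens <- strsplit(s, "[[:space:]]+")[[1]]

  hit <- NULL
  for (tok in tokens) {
    hit <- .resolve_mh_token(tok, reg, species)
    if (!is.null(hit)) break
  }
  if (is.null(hit)) {
    return(.mh_fail(raw, species, "could not resolve to a known MH gene",
                    attempted = tokens[1]))
  }

  fields <- hit$fields
  note <- hit$note
  if (length(fields) > 4L) {
    note <- sprintf("Discarded allele fields beyond the fourth in \"%s\".", raw)
    fields <- fields[1:4]
  }
  keep <- switch(precision, allele = length(fields), protein = min(2L, length(fields)),
                 gene = 0L)
  fields <- if (keep > 0L) fields[seq_len(keep)] else character()

  value <- hit$record$symbol
  if (length(fields) > 0L) value <- paste0(value, "*", paste(fields, collapse = ":"))
  list(value = value, diagnostic = note %||% NA_character_)
}

.resolve_mh_token <- function(tok, reg, species) {
  parts <- strsplit(tok, "*", fixed = TRUE)[[1]]
  root <- parts[1]
  fields <- character()
  if (length(parts) >= 2L) {
    fields <- unlist(strsplit(parts[-1], ":", fixed = TRUE), use.names = FALSE)
    fields <- pad_allele_field(fields[nzchar(fields)])
  }
  if (!nzchar(root)) return(NULL)

  cands <- root
  if (species == "homosapiens" && !startsWith(root, "HLA-")) {
    cands <- c(cands, paste0("HLA-", root))
  }
  if (species == "musmusculus") {
    if (grepl("^H-2", root)) cands <- c(cands, sub("^H-2", "H2-", root))
    if (grepl("^H2[^-]", root)) cands <- c(cands, sub("^H2", "H2-", root))
  }
  for (cand in cands) {
    record <- registry_lookup(reg, cand, locus = "MH")
    if (!is.null(record)) {
      return(list(record = record, fields = fields, note = NULL))
    }
  }
  NULL
}

#' Classify an MH gene as alpha or beta chain
#'
#' @param symbol An MH gene symbol (possibly non-standard).
#' @param species `"homosapiens"` or `"musmusculus"`.
#' @return `"alpha"` or `"beta"`. Unresolvable symbols raise an error, as do
#'   records without chain metadata.
#' @examples
#' mh_get_chain("HLA-A")  # "alpha"
#' mh_get_chain("B2M")    # "beta"
#' @export
mh_get_chain <- function(symbol, species = "homosapiens") {
  rec <- .mh_record_for(symbol, species)
  if (is.na(rec$chain)) {
    stop("Gene \"", rec$symbol, "\" has no chain metadata.", call. = FALSE)
  }
  rec$chain
}

#' Classify an MH gene as class 1 or class 2
#'
#' @inheritParams mh_get_chain
#' @return Integer `1` or `2`.
#' @examples
#' mh_get_class("HLA-DQB1*06:02")  # 2
#' @export
mh_get_class <- function(symbol, species = "homosapiens") {
  rec <- .mh_record_for(symbol, species)
  if (is.na(rec$mh_class)) {
    stop("Gene \"", rec$symbol, "\" has no MH class metadata.", call. = FALSE)
  }
  rec$mh_class
}

.mh_record_for <- function(symbol, species) {
  check_species(species)
  std <- mh_standardize_detail(symbol, species = species, precision = "gene")
  if (is.na(std$value)) {
    stop("Cannot classify: ", std$diagnostic, call. = FALSE)
  }
  registry_lookup(load_reference(species), std$value, locus = "MH")
}

#' Query the catalogue of known MH genes
#'
#' @param species `"homosapiens"` or `"musmusculus"`.
#' @param contains Optional fixed substring the returned symbols must contain.
#' @return Sorted character vector of gene symbols.
#' @export
mh_query <- function(species = "homosapiens", contains = NULL) {
  check_species(species)
  reg <- load_reference(species)
  out <- vapply(Filter(function(r) r$locus == "MH", reg$records),
                `[[`, character(1), "symbol")
  out <- unname(out)
  if (!is.null(contains)) out <- out[grepl(contains, out, fixed = TRUE)]
  sort(unique(out))
}
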