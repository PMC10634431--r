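#' Standardize T cell receptor (TR) gene symbols
#'
#' Converts potentially non-standard TR gene symbols (all four loci: TRA,
#' TRB, TRG, TRD) into their IMGT-compliant form. The resolution pipeline,
#' applied per value: trim and upper-case; if the string contains whitespace,
#' resolve the first whitespace-delimited token that can be resolved and
#' discard the remainder (so `"TRBV5-1*01 or TRBV5-1*02"` yields
#' `"TRBV5-1*01"` and trailing qualifiers such as `"... mutant"` are
#' ignored); split off an allele designation at `"*"` and zero-pad it to two
#' digits; then attempt registry resolution of the root through a fixed
#' most-specific-first cascade of deterministic rewrites (see Details).
#'
#' @details
#' Rewrite cascade, each candidate checked against the registry (canonical
#' symbols first, then deprecated synonyms) before the next is tried:
#' \enumerate{
#'   \item the token as given;
#'   \item leading `"TCR"` replaced by `"TR"`;
#'   \item `"TR"` prepended when the token starts with a locus letter pair
#'     (`AV`, `AJ`, `BV`, `BD`, `BJ`, `GV`, `GJ`, `DV`, `DD`, `DJ`);
#'   \item `"TRAV"` prepended to bare `"n/DVm"` hybrid-locus fragments;
#'   \item legacy annotation suffixes stripped from subfamily ("S") notation
#'     (`TCRBV22S1A2N1T` is reduced to `TCRBV22S1` before synonym lookup);
#'   \item legacy subfamily notation rewritten algebraically:
#'     `rootNSm` to `rootN-m`, and `rootNS1` to `rootN` for single-member
#'     subfamilies (`TCRBV17S1` becomes `TRBV17`);
#'   \item bare-subfamily completion: a member-less subfamily gains `"-1"`
#'     and/or its unique `"/DV..."` hybrid completion
#'     (`TRAV14` resolves to `TRAV14/DV4`).
#' }
#' An allele designation naming an uncatalogued allele of a valid gene
#' degrades to gene-level output with a diagnostic. On failure the value is
#' `NA` and a warning names the input, the species and the attempted fix.
#'
#' @param symbols Character vector of raw gene symbols.
#' @param species `"homosapiens"` (default) or `"musmusculus"`.
#' @param precision `"allele"` (default) keeps any allele designation;
#'   `"gene"` truncates to the gene.
#' @param enforce_functional If `TRUE`, fail symbols whose gene has no
#'   functional (class `F`) allele; when an allele is specified, that allele
#'   itself must be class `F`.
#' @param suppress_warnings Silence per-value diagnostics (see also
#'   `options(imgtidy.suppress_warnings = TRUE)`).
#' @return Character vector of standardized symbols, `NA` where
#'   standardization failed.
#' @examples
#' tr_standardize("aj1")                         # "TRAJ1"
#' tr_standardize("TRBV6-4*01", precision = "gene")  # "TRBV6-4"
#' tr_standardize("TCRBV22S1A2N1T", species = "musmusculus")  # "TRBV2"
#' @export
tr_standardize <- function(symbols, species = "homosapiens",
                           precision = c("allele", "gene"),
                           enforce_functional = FALSE,
                           suppress_warnings = FALSE) {
  res <- tr_standardize_detail(symbols, species = species,
                               precision = precision,
                               enforce_functional = enforce_functional)
  emit_diagnostics(res$diagnostic, suppress = suppress_warnings)
  res$value
}

# Work-horse returning a data.frame(input, value, diagnostic); used by the
# public wrapper, the table/CLI layer and the test suite.
tr_standardize_detail <- function(symbols, species = "homosapiens",
                                  precision = c("allele", "gene"),
                                  enforce_functional = FALSE) {
  check_species(species)
  precision <- match.arg(precision)
  reg <- load_reference(species)
  out <- lapply(as.list(symbols), function(s) {
    .tr_standardize_one(s, reg, species, precision, enforce_functional)
  })
  data.frame(
    input = as.character(symbols),
    value = vapply(out, `[[`, character(1), "value"),
    diagnostic = vapply(out, `[[`, character(1), "diagnostic"),
    stringsAsFactors = FALSE
  )
}

.tr_fail <- function(raw, species, reason, attempted = NULL) {
  raw_txt <- if (is.character(raw) && length(raw) == 1L && !is.na(raw)) raw else "<non-string>"
  msg <- sprintf("Failed to standardize \"%s\" for species %s: %s.",
                 raw_txt, species, reason)
  if (!is.null(attempted)) {
    msg <- paste0(msg, sprintf(" Attempted fix \"%s\".", attempted))
  }
  list(value = NA_character_, diagnostic = msg)
}

.tr_standardize_one <- function(raw, reg, species, precision, enforce_functional) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    return(.tr_fail(raw, species, "input is not a string"))
  }
  s <- toupper(trimws(raw))
  if (!nzchar(s)) {
    return(.tr_fail(raw, species, "input is empty"))
  }
  tokens <- strsplit(s, "[[:space:]]+")[[1]]

  hit <- NULL
  for (tok in tokens) {
    hit <- .resolve_tr_token(tok, reg)
    if (!is.null(hit)) break
  }
  if (is.null(hit)) {
    return(.tr_fail(raw, species, "could not resolve to a known TR gene",
                    attempted = tokens[1]))
  }

  record <- hit$record
  allele <- hit$allele
  note <- hit$note

  if (!is.null(allele) && !allele %in% names(record$alleles)) {
    note <- sprintf(
      "Allele \"*%s\" of \"%s\" is not catalogued for species %s; returning gene-level symbol \"%s\".",
      allele, raw, species, record$symbol)
    allele <- NULL
  }

  if (isTRUE(enforce_functional)) {
    if (!is.null(allele)) {
      if (record$alleles[[allele]] != "F") {
        return(.tr_fail(raw, species,
                        sprintf("allele *%s is not functional", allele),
                        attempted = paste0(record$symbol, "*", allele)))
      }
    } else if (!any(record$alleles == "F")) {
      return(.tr_fail(raw, species, "gene has no functional alleles",
                      attempted = record$symbol))
    }
  }

  value <- record$symbol
  if (precision == "allele" && !is.null(allele)) {
    value <- paste0(value, "*", allele)
  }
  list(value = value, diagnostic = note %||% NA_character_)
}

# Resolve one whitespace-free token to (record, allele designation, note).
.resolve_tr_token <- function(tok, reg) {
  parts <- strsplit(tok, "*", fixed = TRUE)[[1]]
  root <- parts[1]
  allele <- NULL
  note <- NULL
  if (length(parts) >= 2L && nzchar(parts[2])) {
    allele <- pad_allele_field(parts[2])
    if (length(parts) > 2L) {
      note <- sprintf("Dropped extra allele designation(s) in \"%s\".", tok)
    }
  }
  if (!nzchar(root)) return(NULL)

  record <- .resolve_tr_root(root, reg)
  if (is.null(record)) return(NULL)
  list(record = record, allele = allele, note = note)
}

.resolve_tr_root <- function(root, reg) {
  seen <- character()
  try_lookup <- function(cand) {
    if (cand %in% seen) return(NULL)
    seen <<- c(seen, cand)
    registry_lookup(reg, cand, locus = "TR")
  }

  # 1. token as given (canonical or full legacy synonym).
  hit <- try_lookup(root)
  if (!is.null(hit)) return(hit)

  # 2-4. prefix fixes.
  cands <- character()
  if (startsWith(root, "TCR")) cands <- c(cands, sub("^TCR", "TR", root))
  for (base in c(root, cands)) {
    if (grepl("^[ABGD][VDJ]", base)) cands <- c(cands, paste0("TR", base))
  }
  if (grepl("^[0-9]+(-[0-9]+)?/DV", root)) cands <- c(cands, paste0("TRAV", root))
  for (cand in cands) {
    hit <- try_lookup(cand)
    if (!is.null(hit)) return(hit)
  }

  # 5-6. legacy subfamily ("S") notation, most specific first: strip trailing
  # annotation letters (synonym tables key the bare S-form), then rewrite
  # algebraically to root-member, then to the bare root for S1.
  for (cand in unique(c(root, cands))) {
    sm <- regmatches(cand, regexec("^(TC?R[ABGD][VDJ])([0-9]+)S([0-9]+)([A-Z0-9]*)$", cand))[[1]]
    if (length(sm) == 0L) next
    prefix <- sub("^TCR", "TR", sm[2])
    subfam <- sm[3]
    member <- sm[4]
    annot <- sm[5]
    s_cands <- character()
    if (nzchar(annot)) {
      s_cands <- c(s_cands, paste0(sm[2], sm[3], "S", sm[4]),
                   paste0(prefix, subfam, "S", member))
    }
    s_cands <- c(s_cands, paste0(prefix, subfam, "-", member))
    if (member == "1") s_cands <- c(s_cands, paste0(prefix, subfam))
    for (cand2 in s_cands) {
      hit <- try_lookup(cand2)
      if (!is.null(hit)) return(hit)
      hit <- .complete_tr_root(cand2, reg, try_lookup)
      if (!is.null(hit)) return(hit)
    }
  }

  # 7. bare-subfamily completion on all prefix-fixed candidates.
  for (cand in unique(c(root, cands))) {
    hit <- .complete_tr_root(cand, reg, try_lookup)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

# Completion of member-less or hybrid-locus roots: "TRAV14" -> "TRAV14/DV4",
# mouse "TRAV15" -> "TRAV15-1/DV6-1". A "/DV" completion is only taken when
# it is unique in the registry.
.complete_tr_root <- function(cand, reg, try_lookup) {
  if (!grepl("^TR[ABGD][VDJ][0-9]+[DN]?(-[0-9]+)?$", cand)) return(NULL)
  slash_complete <- function(x) {
    hits <- reg$symbols[startsWith(reg$symbols, paste0(x, "/"))]
    if (length(hits) == 1L) registry_lookup(reg, hits, locus = "TR") else NULL
  }
  hit <- slash_complete(cand)
  if (!is.null(hit)) return(hit)
  if (!grepl("-", cand, fixed = TRUE)) {
    dashed <- paste0(cand, "-1")
    hit <- try_lookup(dashed)
    if (!is.null(hit)) return(hit)
    hit <- slash_complete(dashed)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Query the catalogue of known TR genes or alleles
#'
#' @param species `"homosapiens"` or `"musmusculus"`.
#' @param precision `"gene"` (default) returns gene symbols; `"allele"`
#'   returns every catalogued allele as `gene*designation`.
#' @param functionality Optional subset of `c("F", "ORF", "P")`; at gene
#'   precision a gene is kept when any of its alleles has a class in the
#'   filter, at allele precision each allele is filtered individually.
#' @param contains Optional fixed substring the returned symbols must contain.
#' @return Sorted character vector of symbols (no duplicates).
#' @examples
#' "TRAJ1" %in% tr_query("homosapiens", contains = "TRAJ1")
#' @export
tr_query <- function(species = "homosapiens", precision = c("gene", "allele"),
                     functionality = NULL, contains = NULL) {
  check_species(species)
  precision <- match.arg(precision)
  if (!is.null(functionality)) {
    stopifnot(all(functionality %in% c("F", "ORF", "P")))
  }
  reg <- load_reference(species)
  recs <- Filter(function(r) r$locus == "TR", reg$records)
  out <- character()
  for (r in recs) {
    if (precision == "gene") {
      keep <- is.null(functionality) || any(r$alleles %in% functionality)
      if (keep) out <- c(out, r$symbol)
    } else {
      al <- r$alleles
      if (!is.null(functionality)) al <- al[al %in% functionality]
      if (length(al) > 0L) out <- c(out, paste0(r$symbol, "*", names(al)))
    }
  }
  if (!is.null(contains)) out <- out[grepl(contains, out, fixed = TRUE)]
  sort(unique(out))
}

#' Retrieve packaged amino-acid sequence features of a TR gene
#'
#' Returns the per-feature amino-acid sequences stored in the registry for a
#' TR gene (feature labels follow IMGT naming, e.g. `"CDR1-IMGT"`). The
#' symbol is standardized with [tr_standardize()] first, so non-standard
#' input symbols are accepted.
#'
#' Note: the sequences packaged with this version are synthetic illustrative
#' data (see `extdata/tr_aa_sequences_synthetic.tsv`), not IMGT germline
#' sequences; they are valid amino-acid strings intended to exercise the
#' retrieval interface.
#'
#' @param symbol A TR gene symbol (possibly non-standard).
#' @param species `"homosapiens"` or `"musmusculus"`.
#' @return Named character vector mapping feature labels to amino-acid
#'   sequences.
#' @export
tr_get_aa_sequence <- function(symbol, species = "homosapiens") {
  check_species(species)
  std <- tr_standardize_detail(symbol, species = species, precision = "gene")
  if (is.na(std$value)) {
    stop("Cannot retrieve sequence data: ", std$diagnostic, call. = FALSE)
  }
  tab <- .tr_aa_table()
  rows <- tab[tab$species == species & tab$symbol == std$value, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("No sequence data packaged for gene \"", std$value,
         "\" (species ", species, ").", call. = FALSE)
  }
  structure(rows$sequence, names = rows$feature)
}

.tr_aa_table <- function() {
  cached <- .registry_cache[["tr_aa_table"]]
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "tr_aa_sequences_synthetic.tsv",
                      package = "imgtidy", mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE)
  .registry_cache[["tr_aa_table"]] <- tab
  tab
}
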