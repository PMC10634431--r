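#' Load a per-species reference registry of TR and MH genes
#'
#' The registry is the catalogue every standardizer consults: for each
#' canonical IMGT symbol it records the locus (`"TR"` or `"MH"`), the
#' catalogued allele designations with their IMGT functionality class
#' (`F` functional, `ORF` open reading frame, `P` pseudogene), deprecated or
#' legacy synonyms, and, for MH genes, the chain (`alpha`/`beta`) and MH class
#' (`1`/`2`). Registries are packaged as plain TSV files under
#' `inst/extdata` (one TR and one MH file per species) and validated against
#' the schema invariants on every load; loading is cached per session and the
#' returned object should be treated as read-only.
#'
#' The packaged registries are a curated snapshot of the IMGT gene lists for
#' the human and mouse TR loci and the classical MH (HLA / H2) loci.
#' Non-classical MH genes (e.g. MR1, CD1) are deliberately absent, so
#' standardization fails for them.
#'
#' @param species Species identifier, `"homosapiens"` or `"musmusculus"`.
#' @return An object of class `imgt_registry`: a list with elements
#'   `species`, `records` (named list of gene records), `symbols` (character
#'   vector of canonical symbols) and `synonym_index` (named character vector
#'   mapping upper-cased synonyms to canonical symbols).
#' @examples
#' reg <- load_reference("homosapiens")
#' registry_lookup(reg, "TRBV6-4")$symbol
#' @export
load_reference <- function(species) {
  check_species(species)
  cached <- .registry_cache[[species]]
  if (!is.null(cached)) return(cached)

  tr_path <- system.file("extdata", sprintf("tr_%s.tsv", species),
                         package = "imgtidy", mustWork = TRUE)
  mh_path <- system.file("extdata", sprintf("mh_%s.tsv", species),
                         package = "imgtidy", mustWork = TRUE)

  records <- c(
    parse_registry_file(tr_path, locus = "TR"),
    parse_registry_file(mh_path, locus = "MH")
  )
  reg <- build_registry(species, records)
  .registry_cache[[species]] <- reg
  reg
}

.registry_cache <- new.env(parent = emptyenv())

# Parse one packaged registry TSV into a list of gene records.
parse_registry_file <- function(path, locus = c("TR", "MH")) {
  locus <- match.arg(locus)
  df <- utils::read.delim(path, sep = "\t", quote = "", fill = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character())
  required <- if (locus == "TR") c("symbol", "alleles") else
    c("symbol", "chain", "class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("Malformed registry file ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    synonyms <- if ("synonyms" %in% names(df)) row[["synonyms"]] else ""
    synonyms <- toupper(strsplit(synonyms %||% "", "|", fixed = TRUE)[[1]])
    synonyms <- synonyms[nzchar(synonyms) & !is.na(synonyms)]
    alleles <- character()
    if (locus == "TR") {
      parts <- strsplit(row[["alleles"]], "|", fixed = TRUE)[[1]]
      parts <- parts[nzchar(parts)]
      kv <- strsplit(parts, "=", fixed = TRUE)
      alleles <- vapply(kv, function(p) p[2], character(1))
      names(alleles) <- vapply(kv, function(p) p[1], character(1))
    }
    list(
      symbol = row[["symbol"]],
      locus = locus,
      alleles = alleles,
      synonyms = synonyms,
      chain = if (locus == "MH") row[["chain"]] else NA_character_,
      mh_class = if (locus == "MH") as.integer(row[["class"]]) else NA_integer_
    )
  })
}

# Assemble records into a registry, enforcing the schema invariants.
build_registry <- function(species, records) {
  symbols <- vapply(records, `[[`, character(1), "symbol")
  problems <- character()

  if (anyDuplicated(symbols)) {
    problems <- c(problems, paste0(
      "duplicate canonical symbol(s): ",
      paste(unique(symbols[duplicated(symbols)]), collapse = ", ")))
  }
  syn_tab <- data.frame(
    synonym = unlist(lapply(records, `[[`, "synonyms"), use.names = FALSE),
    target = rep(symbols, vapply(records, function(r) length(r$synonyms), integer(1))),
    stringsAsFactors = FALSE
  )
  clash <- intersect(syn_tab$synonym, toupper(symbols))
  if (length(clash) > 0L) {
    problems <- c(problems,
                  paste0("synonym(s) equal to a canonical symbol: ",
                         paste(clash, collapse = ", ")))
  }
  if (anyDuplicated(syn_tab$synonym)) {
    problems <- c(problems, paste0(
      "synonym(s) claimed by more than one record: ",
      paste(unique(syn_tab$synonym[duplicated(syn_tab$synonym)]), collapse = ", ")))
  }
  for (r in records) {
    bad <- names(r$alleles)[!grepl("^[0-9]{2}$", names(r$alleles))]
    if (length(bad) > 0L) {
      problems <- c(problems, paste0(
        r$symbol, ": allele designation(s) not two-digit zero-padded: ",
        paste(bad, collapse = ", ")))
    }
    bad_class <- r$alleles[!r$alleles %in% c("F", "ORF", "P")]
    if (length(bad_class) > 0L) {
      problems <- c(problems, paste0(
        r$symbol, ": unknown functionality class(es): ",
        paste(unique(bad_class), collapse = ", ")))
    }
    if (r$locus == "MH" && !r$chain %in% c("alpha", "beta")) {
      problems <- c(problems, paste0(r$symbol, ": invalid chain \"", r$chain, "\""))
    }
    if (r$locus == "MH" && !r$mh_class %in% c(1L, 2L)) {
      problems <- c(problems, paste0(r$symbol, ": invalid MH class"))
    }
  }
  if (length(problems) > 0L) {
    stop("Registry schema violation for species ", species, ":\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  names(records) <- symbols
  synonym_index <- structure(syn_tab$target, names = syn_tab$synonym)
  structure(
    list(species = species, records = records, symbols = symbols,
         synonym_index = synonym_index),
    class = "imgt_registry"
  )
}

#' Look up a token in a reference registry
#'
#' Case-insensitive resolution primitive used by all standardizers: the
#' upper-cased token is matched first against canonical symbols, then against
#' the deprecated-synonym index. A canonical match always takes priority over
#' a synonym match.
#'
#' @param registry An `imgt_registry` from [load_reference()].
#' @param token A single non-empty string.
#' @param locus Optional locus restriction, `"TR"` or `"MH"`.
#' @return The matching gene record (a list), or `NULL` if the token does not
#'   resolve. `NULL` is the miss signal; no error is raised.
#' @export
registry_lookup <- function(registry, token, locus = NULL) {
  stopifnot(inherits(registry, "imgt_registry"))
  if (!is.character(token) || length(token) != 1L || is.na(token) || !nzchar(token)) {
    return(NULL)
  }
  key <- toupper(token)
  hit <- NULL
  idx <- match(key, toupper(registry$symbols))
  if (!is.na(idx)) {
    hit <- registry$records[[idx]]
  } else {
    canon <- registry$synonym_index[key]
    if (!is.na(canon)) hit <- registry$records[[canon]]
  }
  if (!is.null(hit) && !is.null(locus) && hit$locus != locus) return(NULL)
  hit
}

#' Validate a registry file against the schema
#'
#' Entry point for contributors adding records: parses a TR- or MH-style
#' registry TSV and checks every schema invariant (unique symbols, two-digit
#' allele designations, known functionality classes, no synonym collisions,
#' valid chain/class metadata). Errors list the offending entries.
#'
#' @param path Path to a registry TSV file.
#' @param locus `"TR"` or `"MH"` (which schema the file must satisfy).
#' @param species Label used in error messages only.
#' @return Invisibly `TRUE` if the file is valid; otherwise an error.
#' @export
validate_registry_file <- function(path, locus = c("TR", "MH"),
                                   species = "candidate") {
  locus <- match.arg(locus)
  records <- parse_registry_file(path, locus = locus)
  build_registry(species, records)
  invisible(TRUE)
}

#' @export
print.imgt_registry <- function(x, ...) {
  loci <- vapply(x$records, `[[`, character(1), "locus")
  cat(sprintf(
    "<imgt_registry> species=%s: %d TR genes, %d MH genes, %d synonyms\n",
    x$species, sum(loci == "TR"), sum(loci == "MH"), length(x$synonym_index)))
  invisible(x)
}
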