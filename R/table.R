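# Table-level cleaning of AIRR Rearrangement-style data: standardize chosen
# columns in place and report per-column success rates over unique values.

.KINDS <- c("tr", "mh", "junction", "epitope")

# Dispatch one kind of standardization over raw values with per-value
# species; returns data.frame(input, value, diagnostic).
standardize_by_kind <- function(values, kind, species_vec, precision = "allele",
                                enforce_functional = FALSE,
                                strict_junction = FALSE) {
  kind <- match.arg(kind, .KINDS)
  n <- length(values)
  out <- data.frame(input = as.character(values),
                    value = rep(NA_character_, n),
                    diagnostic = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  if (kind %in% c("junction", "epitope")) {
    res <- if (kind == "junction") {
      junction_standardize_detail(values, strict = strict_junction)
    } else {
      aa_standardize_detail(values)
    }
    out$value <- res$value
    out$diagnostic <- res$diagnostic
    return(out)
  }

  # Gene kinds: unsupported species labels are standardization failures.
  bad_species <- is.na(species_vec)
  out$diagnostic[bad_species] <- sprintf(
    "Failed to standardize \"%s\": species not supported.",
    out$input[bad_species])
  for (sp in unique(species_vec[!bad_species])) {
    sel <- !bad_species & species_vec == sp
    res <- if (kind == "tr") {
      gene_precision <- if (precision %in% c("allele", "gene")) precision else "allele"
      tr_standardize_detail(values[sel], species = sp,
                            precision = gene_precision,
                            enforce_functional = enforce_functional)
    } else {
      mh_standardize_detail(values[sel], species = sp, precision = precision)
    }
    out$value[sel] <- res$value
    out$diagnostic[sel] <- res$diagnostic
  }
  out
}

# Build the per-kind evaluation entry over unique (value, species) pairs.
build_report_entry <- function(detail, kind, n_examples = 10L) {
  unique_values <- nrow(detail)
  standardized <- sum(!is.na(detail$value))
  failures <- detail[is.na(detail$value), c("input", "diagnostic"), drop = FALSE]
  list(
    kind = kind,
    unique_values = unique_values,
    standardized = standardized,
    failed = unique_values - standardized,
    success_fraction = if (unique_values > 0L) standardized / unique_values else NA_real_,
    failure_examples = utils::head(failures, n_examples)
  )
}

#' Standardize columns of a tabular repertoire file
#'
#' Reads a tab- or comma-separated table (dialect chosen by file extension;
#' AIRR Rearrangement TSV with `v_call`, `j_call`, `junction_aa` columns is
#' the primary dialect), replaces each named column with standardized values
#' (empty cell where standardization fails), writes the result, and returns
#' an evaluation report computed over unique values per column (uniqueness
#' taken before standardization). Columns not named pass through unchanged.
#'
#' Per-row species labels in `species_col` are matched case- and
#' space-insensitively (`"Homo sapiens"`, `"homosapiens"`); rows with a
#' missing label fall back to `species`, and rows with an unsupported label
#' count as failures.
#'
#' @param input_path Input table (.tsv/.txt tab-separated, .csv comma).
#' @param output_path Path for the cleaned table (dialect from extension).
#' @param tr_cols,mh_cols Character vectors of gene-symbol column names.
#' @param junction_col,epitope_col Optional sequence column names.
#' @param species Default species for rows without a label.
#' @param species_col Optional name of a per-row species-label column.
#' @param precision Gene resolution: `"allele"`, `"gene"`, or (MH columns
#'   only) `"protein"`.
#' @param enforce_functional Restrict TR columns to functional genes/alleles.
#' @param strict_junction Reject, instead of repairing, unframed junctions.
#' @param report_path Optional path to write the rendered text report.
#' @return An `imgtidy_report` object (invisibly a list of per-column
#'   entries); failures in cells do not raise errors, but a missing file or
#'   column does.
#' @export
standardize_table <- function(input_path, output_path,
                              tr_cols = character(), mh_cols = character(),
                              junction_col = NULL, epitope_col = NULL,
                              species = "homosapiens", species_col = NULL,
                              precision = "allele",
                              enforce_functional = FALSE,
                              strict_junction = FALSE,
                              report_path = NULL) {
  check_species(species)
  tab <- read_table_auto(input_path)

  specs <- c(
    stats::setNames(rep("tr", length(tr_cols)), tr_cols),
    stats::setNames(rep("mh", length(mh_cols)), mh_cols),
    if (!is.null(junction_col)) stats::setNames("junction", junction_col),
    if (!is.null(epitope_col)) stats::setNames("epitope", epitope_col)
  )
  missing_cols <- setdiff(c(names(specs), species_col), names(tab))
  if (length(missing_cols) > 0L) {
    stop("Column(s) not found in ", input_path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  species_vec <- rep(species, nrow(tab))
  if (!is.null(species_col)) {
    lab <- normalize_species_label(tab[[species_col]])
    blank <- is.na(tab[[species_col]]) | !nzchar(trimws(tab[[species_col]]))
    species_vec <- ifelse(blank, species, lab)
  }

  report <- list()
  for (col in names(specs)) {
    kind <- specs[[col]]
    raw <- tab[[col]]
    filled <- !is.na(raw) & nzchar(trimws(raw))
    key_species <- if (kind %in% c("tr", "mh")) species_vec else rep("", nrow(tab))
    key <- paste(raw, key_species, sep = "\r")
    uniq <- !duplicated(key) & filled
    detail <- standardize_by_kind(
      raw[uniq], kind,
      species_vec = if (kind %in% c("tr", "mh")) key_species[uniq] else NULL,
      precision = precision, enforce_functional = enforce_functional,
      strict_junction = strict_junction)
    mapped <- detail$value[match(key, key[uniq])]
    tab[[col]] <- ifelse(filled, ifelse(is.na(mapped), "", mapped), raw)
    report[[col]] <- build_report_entry(detail, kind)
  }

  write_table_auto(tab, output_path)
  report <- structure(report, class = "imgtidy_report")
  if (!is.null(report_path)) {
    writeLines(format(report), report_path)
  }
  invisible(report)
}

#' Evaluate standardization success over an export of raw values
#'
#' Deduplicates the values in a one-column file (optionally with a per-row
#' species-label column), standardizes each unique value at default
#' settings with no functionality restriction, and reports counts, the
#' success fraction and failure examples. An empty input yields a report
#' with zero counts, not an error.
#'
#' @param values_path File of raw values with a header row; `value_col`
#'   defaults to the first column.
#' @param kind One of `"tr"`, `"mh"`, `"junction"`, `"epitope"`.
#' @param species Default species for values without a label.
#' @param species_col,value_col Optional column names.
#' @return An `imgtidy_report` with a single entry.
#' @export
evaluate_export <- function(values_path, kind, species = "homosapiens",
                            species_col = NULL, value_col = NULL) {
  kind <- match.arg(kind, .KINDS)
  check_species(species)
  tab <- read_table_auto(values_path)
  value_col <- value_col %||% names(tab)[1]
  if (!is.null(species_col) && !species_col %in% names(tab)) {
    stop("Column \"", species_col, "\" not found in ", values_path, call. = FALSE)
  }
  raw <- if (nrow(tab) > 0L) tab[[value_col]] else character()

  species_vec <- rep(species, length(raw))
  if (!is.null(species_col) && length(raw) > 0L) {
    lab <- normalize_species_label(tab[[species_col]])
    blank <- is.na(tab[[species_col]]) | !nzchar(trimws(tab[[species_col]]))
    species_vec <- ifelse(blank, species, lab)
  }

  filled <- !is.na(raw) & nzchar(trimws(raw))
  key_species <- if (kind %in% c("tr", "mh")) species_vec else rep("", length(raw))
  key <- paste(raw, key_species, sep = "\r")
  uniq <- !duplicated(key) & filled
  detail <- standardize_by_kind(
    raw[uniq], kind,
    species_vec = if (kind %in% c("tr", "mh")) key_species[uniq] else NULL)
  structure(stats::setNames(list(build_report_entry(detail, kind)), kind),
            class = "imgtidy_report")
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.delim(path, sep = sep, quote = "", colClasses = "character",
                    check.names = FALSE, na.strings = character())
}

write_table_auto <- function(tab, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
}

#' @export
format.imgtidy_report <- function(x, ...) {
  lines <- character()
  for (col in names(x)) {
    e <- x[[col]]
    frac <- if (is.na(e$success_fraction)) "-" else
      sprintf("%.1f%%", 100 * e$success_fraction)
    lines <- c(lines, sprintf(
      "%s [%s]: %d unique values, %d standardized (%s), %d failed",
      col, e$kind, e$unique_values, e$standardized, frac, e$failed))
    if (nrow(e$failure_examples) > 0L) {
      lines <- c(lines, paste0("  failure: ", e$failure_examples$input,
                               "  -- ", e$failure_examples$diagnostic))
    }
  }
  lines
}

#' @export
print.imgtidy_report <- function(x, ...) {
  writeLines(format(x))
  invisible(x)
}
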