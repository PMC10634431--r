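# Shared helpers: quiet standardization wrappers and in-code fixture tables.

std_tr <- function(x, ...) tr_standardize(x, ..., suppress_warnings = TRUE)
std_mh <- function(x, ...) mh_standardize(x, ..., suppress_warnings = TRUE)
std_jx <- function(x, ...) junction_standardize(x, ..., suppress_warnings = TRUE)
std_aa <- function(x, ...) aa_standardize(x, ..., suppress_warnings = TRUE)

write_fixture_table <- function(df, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  utils::write.table(df, path, sep = if (ext == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

# Split generated pairs by kind and run the matching standardizer.
recover_pairs <- function(pairs, species) {
  out <- rep(NA_character_, nrow(pairs))
  tr <- pairs$kind == "tr"
  out[tr] <- std_tr(pairs$messy[tr], species = species)
  out[!tr] <- std_mh(pairs$messy[!tr], species = species)
  out
}
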