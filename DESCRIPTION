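Package: imgtidy
Title: Standardize T Cell Receptor and MHC Gene Nomenclature
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts messy T cell receptor (TR) and major histocompatibility
    (MH/HLA) gene symbols into IMGT-compliant form, validates and repairs
    junction and epitope amino-acid sequences, and ships curated per-species
    reference registries of valid genes, alleles, functionality classes and
    deprecated synonyms for Homo sapiens and Mus musculus. Includes
    table-level cleaning for AIRR Rearrangement-style data (v_call, j_call,
    junction_aa columns) with standardization success reporting, a seeded
    messy-symbol fixture generator for regression testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
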