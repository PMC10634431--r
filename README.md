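# imgtidy

Standardize T cell receptor (TR) and major histocompatibility (MH/HLA) gene
nomenclature, and validate or repair junction (CDR3) and epitope amino-acid
sequences, in R.

TR repertoire datasets from public sources mix deprecated gene symbols
(`TCRBV17S1`), abbreviations (`aj1`, `DQB1*06:02`), legacy mouse H2 names
(`H2-Db`), free-text qualifiers (`HLA-A*02:01 W167A mutant`) and differing
resolution levels (gene vs allele). Downstream analysis needs one canonical,
computer-readable vocabulary. imgtidy resolves messy symbols to their
IMGT-compliant form against curated per-species registries of valid genes,
alleles, functionality classes and deprecated synonyms (*Homo sapiens* and
*Mus musculus*), filters out unresolvable values, and reports how much of a
dataset survived cleaning. Junction sequences are validated against the
20-letter amino-acid alphabet and the conserved C...F/W framing; bare CDR3s
are repaired by adding the framing residues (`sadaf` → `CSADAFF`).

Intended users: immunoinformaticians cleaning AIRR-seq rearrangement tables
or database exports (e.g. IEDB receptor tables) before repertoire analysis.

## Worked example

```r
library(imgtidy)

tr_standardize("aj1")
#> [1] "TRAJ1"
tr_standardize("TRBV6-4*01", precision = "gene")
#> [1] "TRBV6-4"
tr_standardize("TRBV1", enforce_functional = TRUE)
#> Warning: Failed to standardize "TRBV1" for species homosapiens: gene has
#> no functional alleles. Attempted fix "TRBV1".
#> [1] NA
tr_standardize("TCRBV22S1A2N1T", species = "musmusculus")
#> [1] "TRBV2"

mh_standardize("HLA-A*01:01:01", precision = "protein")
#> [1] "HLA-A*01:01"
mh_standardize("CRW2", species = "musmusculus")
#> [1] "MH1-M5"

junction_standardize("sadaf")
#> [1] "CSADAFF"
aa_standardize("VMAPRTLIL")
#> [1] "VMAPRTLIL"

mh_get_chain("HLA-DRB1*04:01")   # "beta"
mh_get_class("HLA-DQB1*06:02")   # 2
"TRAJ1" %in% tr_query("homosapiens", contains = "TRAJ1")  # TRUE
```

`TRAJ1` is the IMGT form recovered from the abbreviation `aj1`; `NA` plus a
warning is the failure signal (here: `TRBV1` has no functional allele, so it
is excluded when `enforce_functional = TRUE`); `TRBV2` is the current IMGT
name behind the legacy mouse designation `TCRBV22S1A2N1T`; protein-level
HLA precision keeps the first two colon-separated allele fields; and the
junction repair wraps a bare CDR3 with the conserved C/F framing residues.

Tables are cleaned column-wise (empty cell = standardization failure), with
a per-column success report over unique values:

```sh
Rscript exec/imgtidy standardize-table \
  --input repertoire.tsv --output repertoire_clean.tsv \
  --tr-col v_call,j_call --junction-col junction_aa \
  --species homosapiens --species-col organism
#> v_call [tr]: 2 unique values, 2 standardized (100.0%), 0 failed
#> junction_aa [junction]: 2 unique values, 2 standardized (100.0%), 0 failed

Rscript exec/imgtidy evaluate --input export.tsv --kind tr
```

The same operations are available in R as `standardize_table()` and
`evaluate_export()`.

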