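---
title: "Standardizing TR and MH gene nomenclature with imgtidy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing TR and MH gene nomenclature with imgtidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imgtidy)
```

## The problem

T cell receptor (TR) repertoire datasets record, for each receptor chain,
which V and J genes were used and the amino-acid sequence of the junction
(CDR3) region, often annotated with the cognate peptide and the presenting
major histocompatibility (MH) protein. Although IMGT defines a standard
nomenclature for TR and MH genes, public datasets mix deprecated symbols
(`TCRBV17S1`), abbreviations (`aj1`, `DQB1*06:02`), legacy mouse H2 names
(`H2-Db`), free-text qualifiers (`HLA-A*02:01 W167A mutant`) and differing
resolution levels (gene vs allele). imgtidy converts such values to their
IMGT-compliant form, filters out values that cannot be resolved, and reports
how much of a dataset survived cleaning.

## The reference registries

All standardizers consult a per-species registry (`load_reference()`): a
catalogue of canonical symbols with, for TR genes, the catalogued allele
designations and their IMGT functionality class (`F` functional, `ORF`,
`P` pseudogene) and, for MH genes, the chain (`alpha`/`beta`) and MH class
(1/2). A synonym index maps deprecated names (mouse `CRW2`, legacy H2
symbols) to canonical records. Only *Homo sapiens* and *Mus musculus* are
supported, with the string identifiers `"homosapiens"` and `"musmusculus"`.

The packaged registries are a hand-curated snapshot of the IMGT gene lists
for the four human and mouse TR loci and the classical MH loci (human HLA
class I/II plus B2M; mouse MH1/MH2 plus B2M). Functionality classes and
allele catalogues are curated best-effort: every symbol exercised in the
documentation and tests is present, gene-level lists are intended to be
complete, but allele-level completeness beyond designation `01` (and `02`
where commonly reported) is not guaranteed. Non-classical MH genes (MR1,
CD1) are deliberately absent so that standardization fails for them.
Contributors can check candidate registry files with
`validate_registry_file()`, which enforces the schema invariants (unique
symbols, two-digit allele designations, no synonym shadowing a canonical
symbol, valid chain/class metadata). B2M is carried as a valid non-HLA
record (class I accessory beta chain) in both species.

The amino-acid feature table behind `tr_get_aa_sequence()` is synthetic
illustrative data (`extdata/tr_aa_sequences_synthetic.tsv`): IMGT germline
sequences are not redistributed with this package, so the retrieval
interface is exercised with clearly-labelled placeholder sequences that are
valid amino-acid strings.

## The TR pipeline

`tr_standardize()` applies, per value: trim and upper-case; if the string
contains whitespace, resolve the first whitespace-delimited token that can
be resolved and discard the rest; split an allele designation at `*` and
zero-pad it to two digits; resolve the root through a deterministic
most-specific-first cascade, checking the registry (canonical symbols, then
synonyms) after every rewrite:

1. the token as given — this is where full legacy synonyms such as mouse
   `TCRBV22S1A2N1T` resolve;
2. `TCR` replaced by `TR`;
3. `TR` prepended to tokens starting with a locus letter pair (`AV`, `BJ`, ...);
4. `TRAV` prepended to bare `n/DVm` hybrid fragments (`29/DV5`);
5. legacy annotation letters stripped back to the bare subfamily "S" form;
6. algebraic S-notation rewrites, `rootNSm` → `rootN-m`, then `rootNS1` →
   `rootN`;
7. bare-subfamily completion: `-1` appended and/or the unique `/DV...`
   hybrid completion taken (`TRAV14` → `TRAV14/DV4`; mouse `TRAV15` →
   `TRAV15-1/DV6-1`).

Design choices worth stating explicitly:

* **Ordering.** Exact and synonym matches of progressively normalized forms
  are always tried before algebraic rewrites. Legacy subfamily numbering
  does not coincide with current IMGT numbering (mouse `TCRBV22S1`
  corresponds to `TRBV2`, not to any `TRBV22`), so the synonym table must
  win over the S-notation algebra whenever both could apply.
* **`"A or B"` inputs resolve to A.** The first resolvable token is
  returned; computing the greatest common factor of the two alternatives is
  deliberately not attempted.
* **Uncatalogued alleles degrade.** `TRBV6-4*99` returns `TRBV6-4` with a
  diagnostic rather than failing: the gene information is sound and failure
  is reserved for unresolvable roots.
* **Insufficient information fails.** Bare digits (`1`) or subfamily
  fragments (`12D-2`) carry no recoverable locus letter and return `NA`.
* **Functionality.** A gene is functional iff at least one catalogued
  allele has class `F`. With `enforce_functional = TRUE` a gene without a
  functional allele fails; when an allele is specified, that allele itself
  must be class `F`.
* **Gamma/delta loci** go through the same pipeline as alpha/beta.

`precision = "gene"` truncates the allele designation. Every failure emits
a diagnostic warning naming the input, species and attempted fix; warnings
can be silenced per call (`suppress_warnings = TRUE`) or globally
(`options(imgtidy.suppress_warnings = TRUE)`), and batch interfaces collect
diagnostics into the report instead.

## The MH pipeline

`mh_standardize()` mirrors the TR pipeline: first-resolvable-token
qualifier stripping, allele fields split at `*`/`:` with two-digit
zero-padding, then root resolution — direct lookup, `HLA-` prepended for
human roots, `H-2`/`H2` legacy rewrites plus the synonym table for mouse.
Precision is `allele` (all fields), `protein` (first two fields — the
common analytical unit of HLA identity), or `gene`. Allele fields beyond
the fourth are discarded with a diagnostic; allele fields of valid roots
are otherwise not validated against an allele catalogue. Class-level
labels (`HLA class II`, `HLA-DQ`) name groups rather than genes, are absent
from the registry as such, and fail. The mouse registry classifies the
H2-D/H2-K loci as class I (`MH1-D1`, `MH1-K1`), which is what the legacy
`H2-Db`/`H-2Kb` names resolve to. `mh_get_chain()` and `mh_get_class()`
expose the registry's chain and class metadata after standardization.

## Junction and epitope sequences

`aa_standardize()` trims, upper-cases, and accepts a value iff every
character is one of the 20 standard amino-acid letters — ambiguity codes
(B, X, Z), gap or modification syntax and digits are rejected.
`junction_standardize()` additionally enforces junction framing (leading
cysteine, trailing phenylalanine or tryptophan). An unframed sequence that
does not start with C is assumed to be a bare CDR3 and is wrapped as
`C...F` (so `sadaf` becomes `CSADAFF`); a C-initial sequence with a bad
terminal residue only gains the trailing `F`. The repair always appends
`F`, never `W` — predicting the true terminal residue from the J gene is
out of scope. With `strict = TRUE` unframed sequences are rejected instead
of repaired. The empty string always fails; a single valid residue (`"A"`)
is wrapped to `CAF` in non-strict mode, and repairs never remove residues
and add at most two.

## Table cleaning and evaluation

`standardize_table()` cleans chosen columns of a TSV/CSV table (AIRR
Rearrangement columns `v_call`, `j_call`, `junction_aa` are the expected
dialect), writing empty cells where standardization fails so that
downstream tools can filter, and reporting per-column success over unique
values (uniqueness taken before standardization; for gene columns a value
is unique per (value, species) pair, for sequence columns per raw string).
Per-row species labels are matched case- and space-insensitively; rows
without a label use the default species (*Homo sapiens*), and rows with an
unsupported label count as failures. `evaluate_export()` applies the same
procedure to a one-column export of raw values. The `exec/imgtidy` script
exposes both as shell subcommands.

## The fixture generator

`generate_messy_pairs()` produces seeded messy-input/expected-output pairs
by applying 1–3 compatible corruption rules (case folding, `TCR` prefixes,
dropped prefixes, qualifier tokens, S-notation, allele unpadding, `A or B`
duplication) to canonical registry symbols. The generator models exactly
the corruption classes the standardizers are documented to repair —
recoverability is by construction, and the test suite asserts 100%
recovery over 1,000 pairs per species. It does not model corruption the
standardizers are documented *not* to handle (ambiguity codes,
non-classical MH, unsupported species); those live as fixed negative
cases. Passing fixture tests therefore demonstrates internal consistency
of the documented repair rules, not performance on arbitrary real-world
mess: real exports contain free-text conventions (serology abbreviations
like `A1`, haplotype shorthand, vendor-specific spellings) beyond the
generated classes.

## Numerical and degenerate-input choices

Standardizers never raise on bad values — `NA` plus a diagnostic is the
failure signal, and errors are reserved for caller mistakes (unknown
species or precision keywords, missing files or columns). Empty and
non-string inputs fail like any unresolvable value. Query results are
sorted for deterministic serialization. Reports define
`success_fraction = standardized / unique_values`, with `NA` for empty
inputs. The generator restores the caller's RNG state, so seeded fixtures
do not perturb the session's random stream.

## Problem sizes used by the checks

The test suite exercises: every worked example from the documentation
(sub-second); all ~520 registry symbols per species for idempotence and
closure; 1,000 seeded fixture pairs per species for round-trip recovery
and precision/functionality invariants; and an exhaustive comparison of
junction accept/repair decisions against an independently written
brute-force predicate over all 406,900 strings of length ≤ 4 on a
25-character alphabet (20 valid plus 5 invalid characters).
`scripts/acceptance.R` recomputes the same quantities from scratch at the
repository root.

## Known limitations

* Only human and mouse; no species inference from symbol shape.
* Serology-style HLA abbreviations (`A1`, `B8`) are resolved only if
  present in the synonym table; the packaged table does not cover the full
  serology catalogue.
* `"A or B"` returns `A`, not the common factor of the alternatives.
* Junction repair always assumes a terminal `F`; no option to strip the
  C/F framing.
* Allele imputation (resolving a gene with a single catalogued allele to
  that allele) is not performed.
* Functionality classes and allele catalogues are a curated snapshot, not
  a live mirror of IMGT.
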