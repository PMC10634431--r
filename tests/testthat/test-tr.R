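test_that("messy TR symbols standardize to their IMGT form", {
  cases <- list(
    # input, species, expected
    list("aj1", "homosapiens", "TRAJ1"),
    list("TRAJ1", "homosapiens", "TRAJ1"),
    list("TCRBV17S1", "homosapiens", "TRBV17"),
    list("29/DV5*01", "homosapiens", "TRAV29/DV5*01"),
    list("TCRBV5-1*01 or TCRBV5-1*02", "homosapiens", "TRBV5-1*01"),
    list("TCRBV22S1A2N1T", "musmusculus", "TRBV2"),
    list("TCRAV14D-3/DV8*02", "musmusculus", "TRAV14D-3/DV8*02"),
    list("TRAV15", "musmusculus", "TRAV15-1/DV6-1"),
    list("trav14", "homosapiens", "TRAV14/DV4"),
    list("  TRBV19  ", "homosapiens", "TRBV19")
  )
  for (cs in cases) {
    expect_identical(std_tr(cs[[1]], species = cs[[2]]), cs[[3]],
                     label = paste("input", cs[[1]]))
  }
})

test_that("unresolvable TR symbols fail with NA and a diagnostic warning", {
  bad_human <- c("TCRAJ1-3", "TRBV14DV4", "")
  for (x in bad_human) {
    expect_warning(res <- tr_standardize(x), "Failed to standardize")
    expect_true(is.na(res))
  }
  bad_mouse <- c("1", "12D-2", "TRVB13-1*02")
  for (x in bad_mouse) {
    expect_warning(res <- tr_standardize(x, species = "musmusculus"),
                   "Failed to standardize")
    expect_true(is.na(res))
  }
  # non-string input is a failure, not an exception
  expect_true(is.na(std_tr(NA)))
  expect_error(tr_standardize("TRAJ1", species = "homo"), "Supported species")
  expect_error(tr_standardize("TRAJ1", precision = "proteome"))
})

test_that("precision, allele padding and uncatalogued-allele degradation", {
  expect_identical(std_tr("TRBV6-4*01", precision = "gene"), "TRBV6-4")
  expect_identical(std_tr("TRBV6-4*1"), "TRBV6-4*01")
  # uncatalogued allele of a valid gene degrades to the gene with a warning
  expect_warning(res <- tr_standardize("TRBV6-4*99"), "not catalogued")
  expect_identical(res, "TRBV6-4")
  # gene precision output equals the root of the allele-precision output
  vals <- c("aj1", "TRBV6-4*01", "TCRBV5-1*01", "29/DV5*01")
  al <- std_tr(vals, precision = "allele")
  ge <- std_tr(vals, precision = "gene")
  expect_identical(ge, sub("\\*.*$", "", al))
})

test_that("enforce_functional rejects genes and alleles without class F", {
  expect_warning(res <- tr_standardize("TRBV1", enforce_functional = TRUE),
                 "gene has no functional alleles")
  expect_true(is.na(res))
  # allele-level granularity: TRBV17*01 is ORF
  expect_warning(res <- tr_standardize("TRBV17*01", enforce_functional = TRUE),
                 "not functional")
  expect_true(is.na(res))
  expect_identical(std_tr("TRBV19", enforce_functional = TRUE), "TRBV19")
  # with the flag off, non-functional genes still standardize
  expect_identical(std_tr("TRBV1"), "TRBV1")
})

test_that("standardization is idempotent on its own outputs", {
  for (sp in c("homosapiens", "musmusculus")) {
    reg <- load_reference(sp)
    tr_symbols <- reg$symbols[vapply(reg$records, `[[`, character(1), "locus") == "TR"]
    once <- std_tr(tr_symbols, species = sp)
    expect_false(anyNA(once))
    expect_identical(std_tr(once, species = sp), once)
  }
})

test_that("TR query respects precision, functionality filters and patterns", {
  q <- tr_query("homosapiens", contains = "TRAJ1")
  expect_true("TRAJ1" %in% q)
  expect_false(any(duplicated(q)))

  functional <- tr_query("homosapiens", functionality = "F")
  expect_false("TRBV1" %in% functional)
  expect_true("TRBV19" %in% functional)

  expect_length(tr_query("homosapiens", contains = "ZZZZ"), 0)

  alleles <- tr_query("homosapiens", precision = "allele", contains = "TRBV6-4")
  expect_setequal(alleles, c("TRBV6-4*01", "TRBV6-4*02"))
  expect_error(tr_query("canisfamiliaris"), "Supported species")
})

test_that("TR amino-acid sequence retrieval round-trips the packaged table", {
  seqs <- tr_get_aa_sequence("TRBV6-4")
  expect_true(all(c("CDR1-IMGT", "CDR2-IMGT") %in% names(seqs)))
  # accepts messy input symbols
  expect_identical(tr_get_aa_sequence("tcrbv6-4"), seqs)
  # every packaged sequence is alphabet-valid (aa standardizer as oracle)
  expect_identical(std_aa(unname(seqs)), unname(seqs))

  expect_error(tr_get_aa_sequence("TCRAJ1-3"), "Failed to standardize")
  expect_error(tr_get_aa_sequence("TRAJ2"), "No sequence data")
})
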