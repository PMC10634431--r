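test_that("table standardization rewrites columns and reports unique-value rates", {
  tab <- data.frame(
    cell_id = c("c1", "c2", "c3", "c4"),
    v_call = c("aj1", "TCRAJ1-3", "TRBV6-4*01", "aj1"),
    junction_aa = c("CASSF", "CSARDW", "CAW", "CSSF"),
    note = c("keep", "these", "cells", "intact"),
    stringsAsFactors = FALSE
  )
  input <- write_fixture_table(tab)
  output <- tempfile(fileext = ".tsv")
  report_path <- tempfile(fileext = ".txt")

  rep <- standardize_table(input, output, tr_cols = "v_call",
                           junction_col = "junction_aa",
                           report_path = report_path)

  # 3 unique v_call values, 2 standardize -> success fraction 2/3
  e <- rep$v_call
  expect_identical(e$unique_values, 3L)
  expect_identical(e$standardized, 2L)
  expect_equal(e$success_fraction, 2 / 3)
  expect_identical(e$standardized + e$failed, e$unique_values)
  expect_identical(e$failure_examples$input, "TCRAJ1-3")

  out <- utils::read.delim(output, colClasses = "character")
  expect_identical(out$v_call, c("TRAJ1", "", "TRBV6-4*01", "TRAJ1"))
  # an all-valid junction column passes through identically at rate 1
  expect_identical(out$junction_aa, tab$junction_aa)
  expect_equal(rep$junction_aa$success_fraction, 1)
  # unspecified columns pass through byte-identical
  expect_identical(out$note, tab$note)
  expect_identical(out$cell_id, tab$cell_id)
  expect_true(any(grepl("66.7%", readLines(report_path))))

  # determinism: identical input and options give byte-identical output
  output2 <- tempfile(fileext = ".tsv")
  standardize_table(input, output2, tr_cols = "v_call",
                    junction_col = "junction_aa")
  expect_identical(readLines(output), readLines(output2))
})

test_that("per-row species labels route values to the right registry", {
  tab <- data.frame(
    mhc = c("CRW2", "DQB1*06:02", "HLA-DRB1*04:01", "B2M"),
    organism = c("Mus musculus", "", "mus musculus", "Homo Sapiens"),
    stringsAsFactors = FALSE
  )
  input <- write_fixture_table(tab, ext = "csv")
  output <- tempfile(fileext = ".csv")
  rep <- standardize_table(input, output, mh_cols = "mhc",
                           species_col = "organism")
  out <- utils::read.csv(output, colClasses = "character")
  # CRW2 resolves under the mouse registry; blank label falls back to human;
  # a human HLA symbol labelled mouse is a failure
  expect_identical(out$mhc, c("MH1-M5", "HLA-DQB1*06:02", "", "B2M"))
  expect_identical(rep$mhc$standardized, 3L)

  # unsupported species labels count as failures
  tab$organism[1] <- "Rattus norvegicus"
  input2 <- write_fixture_table(tab, ext = "csv")
  rep2 <- standardize_table(input2, tempfile(fileext = ".csv"),
                            mh_cols = "mhc", species_col = "organism")
  expect_identical(rep2$mhc$standardized, 2L)
  expect_true(any(grepl("species not supported",
                        rep2$mhc$failure_examples$diagnostic)))
})

test_that("missing files and columns raise errors", {
  expect_error(standardize_table(tempfile(), tempfile(), tr_cols = "v_call"),
               "not found")
  input <- write_fixture_table(data.frame(x = "TRAJ1"))
  expect_error(standardize_table(input, tempfile(), tr_cols = "v_call"),
               "v_call")
  expect_error(evaluate_export(input, kind = "clonotype"))
})

test_that("export evaluation deduplicates, applies default species, and counts", {
  pairs <- generate_messy_pairs("homosapiens", 10, seed = 5, loci = "TR")
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(v = pairs$messy), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rep <- evaluate_export(path, kind = "tr")
  expect_equal(rep$tr$success_fraction, 1)

  # curated failure strings with their species labels all fail
  bad <- data.frame(
    value = c("TCRAJ1-3", "TRBV14DV4", "1", "12D-2", "TRVB13-1*02",
              "HLA class II", "HLA-DQ"),
    species = c("homosapiens", "homosapiens", "musmusculus", "musmusculus",
                "musmusculus", "homosapiens", "homosapiens"),
    stringsAsFactors = FALSE
  )
  tr_bad <- write_fixture_table(bad[1:5, ])
  rep_tr <- evaluate_export(tr_bad, kind = "tr", species_col = "species")
  expect_identical(rep_tr$tr$standardized, 0L)
  expect_equal(rep_tr$tr$success_fraction, 0)
  expect_identical(nrow(rep_tr$tr$failure_examples), 5L)

  # duplicates collapse before counting
  dup <- write_fixture_table(data.frame(v = c("aj1", "aj1", "AJ1")))
  rep_dup <- evaluate_export(dup, kind = "tr")
  expect_identical(rep_dup$tr$unique_values, 2L)

  # empty input yields zero counts, not an error
  empty <- tempfile(fileext = ".tsv")
  writeLines("v", empty)
  rep_empty <- evaluate_export(empty, kind = "junction")
  expect_identical(rep_empty$junction$unique_values, 0L)
  expect_true(is.na(rep_empty$junction$success_fraction))
})
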