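test_that("messy MH symbols standardize to their IMGT form", {
  expect_identical(std_mh("HLA-A*01:01:01", precision = "protein"), "HLA-A*01:01")
  expect_identical(std_mh("HLA-A*01:01"), "HLA-A*01:01")
  expect_identical(std_mh("CRW2", species = "musmusculus"), "MH1-M5")
  expect_identical(std_mh("HLA-A*02:01 W167A mutant"), "HLA-A*02:01")
  expect_identical(std_mh("DQB1*06:02"), "HLA-DQB1*06:02")
  expect_identical(std_mh("B2M"), "B2M")
  expect_identical(std_mh("H2-Q9", species = "musmusculus"), "MH1-Q9")
  # legacy H2-D names map to the class I gene MH1-D1
  expect_identical(std_mh("H2-Db", species = "musmusculus"), "MH1-D1")
  expect_identical(std_mh("H-2Kb", species = "musmusculus"), "MH1-K1")
  expect_identical(std_mh("hla-a*1:1"), "HLA-A*01:01")
})

test_that("class-level labels, non-classical MH and species mismatches fail", {
  bad_human <- c("HLA class II", "HLA-DQ", "human MR1 K43A mutant")
  for (x in bad_human) {
    expect_warning(res <- mh_standardize(x), "Failed to standardize")
    expect_true(is.na(res), label = x)
  }
  bad_mouse <- c("M23I", "HLA-DRB1*04:01")
  for (x in bad_mouse) {
    expect_warning(res <- mh_standardize(x, species = "musmusculus"),
                   "Failed to standardize")
    expect_true(is.na(res), label = x)
  }
  expect_error(mh_standardize("HLA-A", species = "h.sapiens"), "Supported species")
  expect_error(mh_standardize("HLA-A", precision = "chain"))
})

test_that("precision levels nest: gene prefixes protein prefixes allele", {
  inputs <- c("HLA-A*01:01:01:02", "DQB1*06:02", "HLA-B*08", "B2M")
  al <- std_mh(inputs, precision = "allele")
  pr <- std_mh(inputs, precision = "protein")
  ge <- std_mh(inputs, precision = "gene")
  expect_true(all(startsWith(al, pr)))
  expect_true(all(startsWith(pr, ge)))
  # protein precision keeps exactly two fields when two or more are given
  n_fields <- function(x) lengths(regmatches(x, gregexpr(":", x))) +
    as.integer(grepl("\\*", x))
  expect_identical(n_fields(pr[1:2]), c(2L, 2L))
  # fields beyond the fourth are discarded with a diagnostic
  expect_warning(res <- mh_standardize("HLA-A*01:01:01:01:99"),
                 "beyond the fourth")
  expect_identical(res, "HLA-A*01:01:01:01")
})

test_that("MH standardization is idempotent on its own outputs", {
  for (sp in c("homosapiens", "musmusculus")) {
    syms <- mh_query(sp)
    once <- std_mh(syms, species = sp)
    expect_false(anyNA(once))
    expect_identical(std_mh(once, species = sp), once)
  }
})

test_that("chain and class metadata queries classify MH genes", {
  expect_identical(mh_get_chain("HLA-A"), "alpha")
  expect_identical(mh_get_chain("B2M"), "beta")
  expect_identical(mh_get_chain("HLA-DRB1*04:01"), "beta")
  expect_identical(mh_get_chain("H2-Q9", species = "musmusculus"), "alpha")

  expect_identical(mh_get_class("MH1-Q9", species = "musmusculus"), 1L)
  expect_identical(mh_get_class("HLA-DQB1*06:02"), 2L)
  expect_identical(mh_get_class("HLA-A*02:01"), 1L)
  expect_identical(mh_get_class("B2M"), 1L)

  expect_error(mh_get_chain("MR1"), "Cannot classify")
  expect_error(mh_get_class("not-a-gene"), "Cannot classify")
})

test_that("MH query is species-sound and supports substring patterns", {
  expect_true("HLA-A" %in% mh_query("homosapiens", contains = "HLA-A"))
  expect_false(any(grepl("^HLA-", mh_query("musmusculus"))))
  expect_length(mh_query("homosapiens", contains = "ZZZZ"), 0)
})
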