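# Deterministic corruption rules modelling the messy-symbol classes the
# standardizers repair: case folding, legacy TCR prefixes, dropped prefixes,
# free-text qualifiers, legacy subfamily ("S") notation, unpadded allele
# designations and "A or B" duplications.

CORRUPTION_RULES <- c("lowercase", "tcr_prefix", "drop_prefix",
                      "add_qualifier", "s_notation", "allele_unpad",
                      "or_duplicate")

# Application order when several rules are combined in one trace: structural
# rewrites first, then decorations, case folding last (so "TRAJ1" under
# drop_prefix + lowercase renders as "aj1").
.RULE_ORDER <- c("s_notation", "tcr_prefix", "drop_prefix", "allele_unpad",
                 "or_duplicate", "add_qualifier", "lowercase")

#' Apply a deterministic corruption rule to a canonical gene symbol
#'
#' Used to build messy-input/expected-output pairs for round-trip testing of
#' the standardizers. Every rule is deterministic given the symbol, and every
#' rule's output differs from its input.
#'
#' @param symbol A canonical gene symbol from a registry.
#' @param rules One or more rule identifiers (applied in a fixed canonical
#'   order regardless of the order given): `"lowercase"`, `"tcr_prefix"`
#'   (TR genes: `TR` to `TCR`), `"drop_prefix"` (remove leading `TR` /
#'   `HLA-`), `"add_qualifier"` (append a `" mutant"`-style token),
#'   `"s_notation"` (render `root-m` as `rootSm`, `root` as `rootS1`),
#'   `"allele_unpad"` (append an unpadded allele designation, `*1` for TR,
#'   `*1:1` for MH), `"or_duplicate"` (render `A` as `"A or A*02"`).
#' @param locus `"TR"` or `"MH"`.
#' @return The corrupted string.
#' @examples
#' corrupt_symbol("TRAJ1", c("drop_prefix", "lowercase"), "TR")   # "aj1"
#' corrupt_symbol("TRBV17", c("s_notation", "tcr_prefix"), "TR")  # "TCRBV17S1"
#' @export
corrupt_symbol <- function(symbol, rules, locus = c("TR", "MH")) {
  locus <- match.arg(locus)
  stopifnot(is.character(symbol), length(symbol) == 1L, length(rules) >= 1L)
  unknown <- setdiff(rules, CORRUPTION_RULES)
  if (length(unknown) > 0L) {
    stop("Unknown corruption rule(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rules <- .RULE_ORDER[.RULE_ORDER %in% rules]
  out <- symbol
  for (rule in rules) {
    if (!rule_applicable(symbol, rule, locus)) {
      stop("Rule \"", rule, "\" is not applicable to ", locus, " symbol \"",
           symbol, "\".", call. = FALSE)
    }
    out <- switch(rule,
      lowercase = tolower(out),
      tcr_prefix = sub("^TR", "TCR", out),
      drop_prefix = if (locus == "TR") sub("^TR", "", out) else sub("^HLA-", "", out),
      add_qualifier = paste(out, "mutant"),
      s_notation = {
        m <- regmatches(out, regexec("^(TR[ABGD][VDJ][0-9]+)(-([0-9]+))?$", out))[[1]]
        if (nzchar(m[4])) paste0(m[2], "S", m[4]) else paste0(m[2], "S1")
      },
      allele_unpad = if (locus == "TR") paste0(out, "*1") else paste0(out, "*1:1"),
      or_duplicate = paste(out, "or", paste0(out, "*02"))
    )
  }
  if (identical(out, symbol)) {
    stop("Corruption left symbol \"", symbol, "\" unchanged.", call. = FALSE)
  }
  out
}

# Applicability of a rule to a symbol; mutual-exclusion constraints between
# rules are handled in generate_messy_pairs().
rule_applicable <- function(symbol, rule, locus, registry = NULL) {
  switch(rule,
    lowercase = grepl("[A-Z]", symbol),
    tcr_prefix = locus == "TR" && startsWith(symbol, "TR"),
    drop_prefix = if (locus == "TR") startsWith(symbol, "TR") else
      startsWith(symbol, "HLA-"),
    add_qualifier = TRUE,
    or_duplicate = TRUE,
    s_notation = locus == "TR" &&
      grepl("^TR[ABGD][VDJ][0-9]+(-[0-9]+)?$", symbol),
    allele_unpad = {
      if (locus == "TR") {
        # Structurally applicable to any allele-less TR symbol; when a
        # registry is supplied, additionally require that allele 01 is
        # catalogued so the expected output stays recoverable.
        !grepl("*", symbol, fixed = TRUE) &&
          (is.null(registry) || {
            rec <- registry_lookup(registry, symbol, locus = "TR")
            !is.null(rec) && "01" %in% names(rec$alleles)
          })
      } else {
        startsWith(symbol, "HLA-")
      }
    },
    FALSE
  )
}

#' Generate seeded messy-symbol/expected-output fixture pairs
#'
#' Samples canonical TR and MH gene symbols from the species registry,
#' applies 1-3 compatible corruption rules to each, and records the expected
#' standardization result. The appropriate standardizer (default options)
#' recovers `expected` from `messy` for every pair by construction; the test
#' suite asserts this at 100%.
#'
#' @param species `"homosapiens"` or `"musmusculus"`.
#' @param n Number of pairs (>= 1).
#' @param seed Integer seed; the same seed yields an identical list.
#' @param loci Which loci to sample from (default both TR and MH).
#' @return A data.frame with columns `messy`, `expected`, `kind` (`"tr"` or
#'   `"mh"`), `species` and `rule_trace` (comma-joined rule ids).
#' @examples
#' pairs <- generate_messy_pairs("homosapiens", n = 5, seed = 7)
#' all(tr_standardize(pairs$messy[pairs$kind == "tr"],
#'                    suppress_warnings = TRUE) ==
#'     pairs$expected[pairs$kind == "tr"])
#' @export
generate_messy_pairs <- function(species, n, seed, loci = c("TR", "MH")) {
  check_species(species)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  loci <- match.arg(loci, several.ok = TRUE)
  reg <- load_reference(species)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  pool <- Filter(function(r) r$locus %in% loci, reg$records)
  symbols <- vapply(pool, `[[`, character(1), "symbol")
  pool_locus <- vapply(pool, `[[`, character(1), "locus")

  rows <- vector("list", n)
  made <- 0L
  while (made < n) {
    i <- sample.int(length(symbols), 1L)
    sym <- symbols[[i]]
    locus <- pool_locus[[i]]
    applicable <- CORRUPTION_RULES[vapply(
      CORRUPTION_RULES, rule_applicable, logical(1),
      symbol = sym, locus = locus, registry = reg)]
    # drop_prefix and tcr_prefix rewrite the same prefix; never combine.
    k <- sample(1:3, 1L)
    rules <- character()
    for (r in sample(applicable)) {
      if (length(rules) == k) break
      if (r == "tcr_prefix" && "drop_prefix" %in% rules) next
      if (r == "drop_prefix" && "tcr_prefix" %in% rules) next
      rules <- c(rules, r)
    }
    if (length(rules) == 0L) next
    messy <- corrupt_symbol(sym, rules, locus)
    expected <- sym
    if ("allele_unpad" %in% rules) {
      expected <- paste0(sym, if (locus == "TR") "*01" else "*01:01")
    }
    made <- made + 1L
    rows[[made]] <- data.frame(
      messy = messy, expected = expected,
      kind = tolower(locus), species = species,
      rule_trace = paste(.RULE_ORDER[.RULE_ORDER %in% rules], collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write fixture pairs to a two-column TSV
#'
#' Emits `messy` and `expected` columns for use as CLI test input.
#'
#' @param pairs A data.frame from [generate_messy_pairs()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_messy_pairs <- function(pairs, path) {
  stopifnot(all(c("messy", "expected") %in% names(pairs)))
  utils::write.table(pairs[, c("messy", "expected")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
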