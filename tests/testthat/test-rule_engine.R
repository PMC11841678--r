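# Rule extraction from reactant-product pairs and the mass-delta index.

test_that("dehydrogenation rule: hydroxyl-bearing ring carbon center, -2.0157 Da", {
  rules <- extract_rules("OC1CCCCC1", "O=C1CCCCC1")
  expect_length(rules, 1L)
  r <- rules[[1]]
  expect_equal(r$mass_delta, -2.0157, tolerance = 1e-3)
  expect_match(r$center_code, "^Cr")            # ring carbon center
  expect_true("Oc[sC]" %in% r$neighbor_codes)   # bonded hydroxyl oxygen
  kinds <- sort(vapply(r$ops, `[[`, character(1), "kind"))
  expect_identical(kinds, c("add", "remove"))
})

test_that("demethylation rule: exocyclic CH3 removed, -14.0157 Da", {
  rules <- extract_rules("Cc1ccccc1", "c1ccccc1")
  expect_length(rules, 1L)
  r <- rules[[1]]
  expect_equal(r$mass_delta, -14.0157, tolerance = 1e-3)
  expect_match(r$center_code, "^Ca")            # aromatic attachment carbon
  expect_identical(r$ops[[1]]$kind, "remove")
  expect_identical(r$ops[[1]]$frag, "C")
})

test_that("identical molecules yield no rule", {
  rules <- extract_rules("CCO", "OCC")
  expect_length(rules, 0L)
})

test_that("rule table holds both directions, deduplicates, and indexes by unit delta", {
  pairs <- data.frame(
    pair_id = c("a", "b"),
    reactant_smiles = c("OC1CCCCC1", "OC1CCCC1"),   # cyclohexanol, cyclopentanol
    product_smiles = c("O=C1CCCCC1", "O=C1CCCC1"),
    stringsAsFactors = FALSE)
  tab <- build_rule_table(pairs, verbose = FALSE)
  expect_setequal(names(tab$index), c("-2", "2"))   # forward and reverse keys
  # the two ring sizes give the same local environment: rules deduplicate
  expect_identical(length(tab$rules), 2L)
  deltas <- vapply(tab$rules, `[[`, numeric(1), "mass_delta")
  expect_setequal(round_half_away(deltas), c(-2L, 2L))

  # every rule reachable through exactly one index key
  ids <- unlist(tab$index)
  expect_setequal(ids, names(tab$rules))
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("match_rules works on unit-rounded deltas; empty result is legal", {
  pairs <- data.frame(pair_id = "a", reactant_smiles = "Cc1ccccc1",
                      product_smiles = "c1ccccc1", stringsAsFactors = FALSE)
  tab <- build_rule_table(pairs, verbose = FALSE)
  hit <- match_rules(tab, -14.02)
  expect_gt(length(hit), 0L)
  expect_true(all(vapply(hit, function(r) round_half_away(r$mass_delta) == -14L,
                         logical(1))))
  expect_length(match_rules(tab, 0.4), 0L)
  expect_length(match_rules(tab, -15.6), 0L)      # rounds to -16, no key
  # rounding is half-away-from-zero: -13.5 rounds to -14
  expect_gt(length(match_rules(tab, -13.5)), 0L)
})

test_that("empty and degenerate tables behave", {
  tab <- build_rule_table(NULL)
  expect_identical(length(tab$rules), 0L)
  expect_length(match_rules(tab, 16), 0L)
  expect_warning(
    tab0 <- build_rule_table(data.frame(pair_id = "x", reactant_smiles = "bad(",
                                        product_smiles = "CCO",
                                        stringsAsFactors = FALSE),
                             verbose = FALSE),
    "skipping invalid structure")
  expect_identical(length(tab0$rules), 0L)
})

test_that("rule tables round-trip through versioned JSON", {
  b <- test_benchmark()
  path <- withr_local_tempfile()
  write_rule_table(b$table, path)
  tab2 <- read_rule_table(path)
  expect_identical(names(tab2$rules), names(b$table$rules))
  expect_identical(tab2$index, b$table$index)
  r1 <- b$table$rules[[1]]
  r2 <- tab2$rules[[r1$id]]
  expect_identical(r2$center_code, r1$center_code)
  expect_identical(r2$neighbor_codes, r1$neighbor_codes)
  expect_equal(r2$mass_delta, r1$mass_delta, tolerance = 1e-12)
  # matching behaves identically after the round trip
  expect_identical(
    vapply(match_rules(tab2, -2.01), `[[`, character(1), "id"),
    vapply(match_rules(b$table, -2.01), `[[`, character(1), "id"))
  expect_error(read_rule_table(withr_local_tempfile()), "not found")
})

test_that("reversibility: for every fixture-derived key k, key -k exists", {
  b <- test_benchmark()
  keys <- as.integer(names(b$table$index))
  expect_setequal(keys, -keys)
})
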