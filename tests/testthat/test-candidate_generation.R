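# Rule application at compatible sites and candidate assembly.

test_that("symmetric sites deduplicate: benzene hydroxylation gives exactly phenol", {
  rules <- extract_rules("c1ccccc1", "Oc1ccccc1")
  cands <- apply_rule("c1ccccc1", rules[[1]])
  expect_identical(nrow(cands), 1L)
  expect_identical(inchikey14(cands$inchikey[1]),
                   inchikey14(canonicalize("Oc1ccccc1")))
  # all six equivalent ring positions retained as provenance of one candidate
  prov <- candidate_provenance(cands)[[1]]
  expect_identical(nrow(prov), 6L)
  expect_setequal(prov$site_atom, 0:5)
})

test_that("a rule whose center is absent from the anchor yields nothing", {
  rules <- extract_rules("OC1CCCCC1", "O=C1CCCCC1")
  cands <- apply_rule("c1ccccc1", rules[[1]])   # benzene has no hydroxyl carbon
  expect_identical(nrow(cands), 0L)
})

test_that("generate_candidates joins rule lookup and application", {
  b <- test_benchmark()
  tab <- active_rule_table(b)
  p <- b$pairs[[1]]
  cands <- generate_candidates(p, tab)
  expect_gt(nrow(cands), 0L)
  truth14 <- inchikey14(p$suspect_annotation)
  expect_true(truth14 %in% substr(cands$inchikey, 1, 14))
  # no table key for the observed delta: empty set is legal
  fake <- p
  fake$mass_difference <- 0.4
  expect_identical(nrow(generate_candidates(fake, tab)), 0L)
})

test_that("mass conservation holds for every candidate of the benchmark", {
  b <- test_benchmark()
  tab <- active_rule_table(b)
  for (p in b$pairs) {
    cands <- generate_candidates(p, tab)
    prov <- candidate_provenance(cands)
    for (j in seq_len(nrow(cands))) {
      deltas <- vapply(prov[[j]]$rule_id,
                       function(rid) tab$rules[[rid]]$mass_delta, numeric(1))
      expect_true(any(abs(cands$mass[j] - p$anchor$monoisotopic_mass - deltas)
                      <= 1e-3),
                  label = sprintf("mass conservation for %s under %s",
                                  cands$inchikey[j], p$anchor_id))
    }
  }
})

test_that("candidate generation is deterministic", {
  b <- test_benchmark()
  tab <- active_rule_table(b)
  p <- b$pairs[[2]]
  c1 <- generate_candidates(p, tab)
  c2 <- generate_candidates(p, tab)
  expect_identical(c1, c2)
  expect_identical(candidate_provenance(c1), candidate_provenance(c2))
})

test_that("duplicate derivatives across rules merge with full provenance", {
  # two rules (distinct ids, same aromatic-CH methylation edit) applied to
  # benzene generate the same derivative: one candidate, both provenances
  r1 <- extract_rules("c1ccccc1", "Cc1ccccc1")[[1]]
  r2 <- r1
  r2$id <- "other_rule"
  tasks <- list(list(anchor = canonicalize("c1ccccc1"), rules = list(r1, r2)))
  cands <- bamanno:::apply_rules_batch(tasks)[[1]]
  toluene14 <- inchikey14(canonicalize("Cc1ccccc1"))
  hit <- substr(cands$inchikey, 1, 14) == toluene14
  expect_identical(sum(hit), 1L)
  expect_identical(nrow(cands), 1L)
  prov <- candidate_provenance(cands)[[which(hit)]]
  expect_setequal(unique(prov$rule_id), c(r1$id, "other_rule"))
})
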