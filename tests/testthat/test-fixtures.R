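# Synthetic data generation: reaction pairs, pseudo-spectra, benchmarks.

test_that("reaction-pair generator reproduces the catalogue chemistry", {
  rp <- suppressMessages(make_reaction_pairs(
    families = c("dehydrogenation", "hydroxylation"),
    scaffolds = c(cyclohexanol = "OC1CCCCC1", benzene = "c1ccccc1"),
    seed = 3))
  expect_true(all(c("dehydrogenation_cyclohexanol", "hydroxylation_benzene")
                  %in% rp$pair_id))
  de <- rp[rp$pair_id == "dehydrogenation_cyclohexanol", ]
  expect_identical(inchikey14(canonicalize(de$product_smiles)),
                   inchikey14(canonicalize("O=C1CCCCC1")))
  hy <- rp[rp$pair_id == "hydroxylation_benzene", ]
  expect_identical(inchikey14(canonicalize(hy$product_smiles)),
                   inchikey14(canonicalize("Oc1ccccc1")))
  # realized deltas match the catalogue
  fams <- biotransformation_families()
  mols <- molecules(unique(c(rp$reactant_smiles, rp$product_smiles)))
  for (i in seq_len(nrow(rp))) {
    want <- fams$mass_delta[fams$family == rp$family[i]]
    got <- mols[[rp$product_smiles[i]]]$monoisotopic_mass -
      mols[[rp$reactant_smiles[i]]]$monoisotopic_mass
    expect_equal(got, want, tolerance = 1e-3)
  }
  # empty scaffold list -> empty output
  expect_identical(nrow(make_reaction_pairs(scaffolds = character(0))), 0L)
})

test_that("simulated spectra are deterministic and structure-aware", {
  s1 <- simulate_spectrum("CC(=O)Nc1ccc(O)cc1")
  s2 <- simulate_spectrum("CC(=O)Nc1ccc(O)cc1", seed = 999)
  expect_identical(s1$peaks, s2$peaks)           # seed is irrelevant by design
  expect_gt(nrow(s1$peaks), 2)
  expect_true(all(diff(s1$peaks[, "mz"]) > 0))

  # single-heavy-atom molecule: one peak at the precursor
  s <- simulate_spectrum("C")
  expect_identical(nrow(s$peaks), 1L)
  expect_equal(unname(s$peaks[1, "mz"]), s$precursor_mz)

  # a localized modification keeps spectral similarity high relative to an
  # unrelated molecule (the premise modified cosine rewards)
  anchor <- simulate_spectrum("CC(CCC(=O)O)C1CCC2C1(C)C(O)CC1C2C(O)CC2CC(O)CCC12C")
  related <- simulate_spectrum("CC(CCC(=O)O)C1CCC2C1(C)C(O)CC1C2C(O)CC2CC(=O)CCC12C")
  unrelated <- simulate_spectrum("Cn1cnc2c1c(=O)n(C)c(=O)n2C")
  expect_gt(modified_cosine(anchor, related)$score,
            modified_cosine(anchor, unrelated)$score)
})

test_that("benchmarks regenerate identically under a seed", {
  b1 <- test_benchmark()
  b2 <- suppressMessages(make_benchmark(12, seed = 101))
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$rule_pairs, b2$rule_pairs)
  expect_identical(names(b1$table$rules), names(b2$table$rules))
  expect_identical(lapply(b1$spectra, `[[`, "peaks"),
                   lapply(b2$spectra, `[[`, "peaks"))
  # and a different seed gives a different pair selection
  b3 <- suppressMessages(make_benchmark(12, seed = 202))
  expect_false(identical(b1$truth$pair_id, b3$truth$pair_id))
})

test_that("benchmark pairs clear the network threshold and carry consistent deltas", {
  b <- test_benchmark()
  for (p in b$pairs) {
    expect_gt(p$edge_score, 0.8)
    expect_equal(p$mass_difference,
                 p$suspect_annotation$monoisotopic_mass -
                   p$anchor$monoisotopic_mass, tolerance = 1e-4)
  }
})

test_that("withholding rules creates unexplainable queries", {
  b <- suppressMessages(make_benchmark(6, seed = 11, withhold_fraction = 1))
  expect_identical(length(b$withheld_rule_ids), length(b$table$rules))
  tab <- active_rule_table(b)
  expect_identical(length(tab$rules), 0L)
  ev <- evaluate(b$pairs, tab, uniform_site_scorer())
  expect_identical(ev$n_with_derivatives, 0L)
  expect_identical(ev$recall, 0)
})

test_that("fixture files are written as plain text and re-readable", {
  b <- test_benchmark()
  dir <- file.path(tempdir(), "bam_fixture_io")
  write_fixtures(b, dir)
  expect_true(all(file.exists(file.path(
    dir, c("spectra.mgf", "rules.json", "rule_pairs.tsv", "pairs.tsv",
           "truth.tsv", "withheld_rules.txt")))))
  sp <- read_spectra(file.path(dir, "spectra.mgf"))
  expect_length(sp, length(b$spectra))
  expect_true(all(vapply(sp, function(s) !is.null(s$annotation), logical(1))))
  tab <- read_rule_table(file.path(dir, "rules.json"))
  expect_identical(names(tab$rules), names(b$table$rules))
})
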