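# Molecule identity, mass and similarity primitives.

test_that("canonicalization is notation-invariant and idempotent", {
  a <- canonicalize("CCO")
  b <- canonicalize("OCC")
  expect_identical(a$smiles, b$smiles)
  expect_identical(a$inchikey, b$inchikey)
  expect_identical(canonicalize(a$smiles)$smiles, a$smiles)
  validate_molecule(a)
})

test_that("monoisotopic mass matches a per-atom summation oracle", {
  m <- canonicalize("C1CC1C")
  expect_equal(m$monoisotopic_mass, 56.0626, tolerance = 1e-3)
  # larger set: every scaffold and every fixture product, against an
  # independent element-mass-table oracle
  rp <- test_reaction_pairs()
  mols <- molecules(unique(c(rp$reactant_smiles, rp$product_smiles)))
  expect_gt(length(mols), 50)
  for (mol in mols) {
    expect_equal(mol$monoisotopic_mass, formula_mass(mol$formula),
                 tolerance = 1e-4)
  }
})

test_that("parse and valence failures raise distinct structured errors", {
  expect_error(canonicalize("not_a_smiles"), class = "bam_parse_error")
  expect_error(canonicalize("C(C)(C)(C)(C)C"), class = "bam_valence_error")
  expect_warning(out <- molecules(c("CCO", "not_a_smiles"), on_error = "skip"),
                 "skipping")
  expect_length(out, 1L)
})

test_that("InChIKey first-block matching ignores stereochemistry", {
  l_ala <- canonicalize("N[C@@H](C)C(=O)O")
  d_ala <- canonicalize("N[C@H](C)C(=O)O")
  expect_false(identical(l_ala$inchikey, d_ala$inchikey))
  expect_true(inchikey14_match(l_ala, d_ala))
  expect_true(inchikey14_match(canonicalize("CCO"), canonicalize("OCC")))
  expect_false(inchikey14_match(canonicalize("CCO"), canonicalize("COC")))
  expect_identical(nchar(inchikey14(l_ala)), 14L)
})

test_that("tanimoto is symmetric, bounded, and 1 for identical molecules", {
  mols <- molecules(unname(bam_scaffolds()[1:8]))
  for (m in mols) expect_equal(tanimoto(m, m), 1.0)
  for (i in 1:4) {
    a <- mols[[i]]
    b <- mols[[9 - i]]
    s <- tanimoto(a, b)
    expect_identical(s, tanimoto(b, a))
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
  # mismatched fingerprint parameters are refused
  broken <- mols[[1]]
  broken$fp_meta <- c(radius = 3, nbits = 1024)
  expect_error(tanimoto(mols[[2]], broken), class = "bam_fp_error")
})
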