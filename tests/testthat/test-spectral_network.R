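# Modified cosine, network construction and anchor-suspect pair derivation.

test_that("modified cosine: self-similarity, shifted identity, and no-match", {
  s <- spectrum("s", 300, cbind(c(100, 150, 210), c(1, 4, 2)))
  expect_equal(modified_cosine(s, s)$score, 1.0, tolerance = 1e-12)

  a <- spectrum("a", 300, cbind(c(100, 200), c(1, 1)))
  b <- spectrum("b", 350, cbind(c(150, 250), c(1, 1)))  # everything +50
  mc <- modified_cosine(a, b)
  expect_equal(mc$score, 1.0, tolerance = 1e-12)
  expect_identical(mc$n_matched_peaks, 2L)

  far <- spectrum("f", 300, cbind(c(111.3, 177.7), c(1, 1)))
  expect_equal(modified_cosine(a, far)$score, 0)
  expect_error(modified_cosine(a, b, fragment_tol = 0), "fragment_tol")
})

test_that("modified cosine equals the exhaustive pairing oracle", {
  set.seed(42)
  for (rep in 1:60) {
    pr <- random_spectrum_pair(max_peaks = 8)
    got <- modified_cosine(pr$a, pr$b)$score
    want <- oracle_modified_cosine(pr$a, pr$b)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("modified cosine is symmetric", {
  set.seed(7)
  for (rep in 1:25) {
    pr <- random_spectrum_pair()
    expect_equal(modified_cosine(pr$a, pr$b)$score,
                 modified_cosine(pr$b, pr$a)$score, tolerance = 1e-9)
  }
})

test_that("build_network keeps only edges strictly above threshold, once, order-invariantly", {
  s1 <- spectrum("n1", 300, cbind(c(100, 150, 210), c(1, 4, 2)))
  s2 <- spectrum("n2", 350, cbind(c(150, 200, 260), c(1, 4, 2)))  # s1 + 50
  s3 <- spectrum("n3", 500, cbind(c(77.7, 391.1), c(1, 1)))       # unrelated
  edges <- build_network(list(s1, s2, s3), threshold = 0.8)
  expect_identical(nrow(edges), 1L)
  expect_identical(edges$spectrum_id_a, "n1")
  expect_identical(edges$spectrum_id_b, "n2")
  # input order must not matter
  edges2 <- build_network(list(s3, s2, s1), threshold = 0.8)
  expect_identical(edges, edges2)
  # strictness: a self-identical pair scores 1, never retained at threshold 1
  expect_identical(nrow(build_network(list(s1, s2), threshold = 1)), 0L)
  expect_identical(nrow(build_network(list(s1), threshold = 0.5)), 0L)
  expect_error(build_network(list(s1, s1)), "duplicate")
})

test_that("derive_pairs implements the annotation and uniqueness rules", {
  eth <- canonicalize("CCO")
  eth_st <- canonicalize("OCC")            # same 2D structure
  ald <- canonicalize("CC=O")
  s1 <- spectrum("p1", 300, cbind(c(100, 150), c(1, 1)), annotation = eth)
  s2 <- spectrum("p2", 350, cbind(c(150, 200), c(1, 1)), annotation = ald)
  s3 <- spectrum("p3", 352, cbind(c(150, 200), c(1, 1)))
  s4 <- spectrum("p4", 299, cbind(c(100, 150), c(1, 1)), annotation = eth_st)
  edge <- function(a, b) data.frame(spectrum_id_a = a, spectrum_id_b = b,
                                    score = 0.9, n_matched_peaks = 2L,
                                    stringsAsFactors = FALSE)
  spectra <- list(s1, s2, s3, s4)

  # both annotated, distinct: two directed pairs with opposite deltas
  pr <- derive_pairs(edge("p1", "p2"), spectra)
  expect_length(pr, 2L)
  expect_identical(pr[[1]]$anchor_id, "p1")
  expect_identical(pr[[2]]$anchor_id, "p2")
  expect_equal(pr[[1]]$mass_difference, -pr[[2]]$mass_difference)
  expect_equal(pr[[1]]$mass_difference,
               neutral_mass(s2) - neutral_mass(s1), tolerance = 1e-9)

  # one annotated endpoint: annotated node anchors
  pr <- derive_pairs(edge("p1", "p3"), spectra)
  expect_length(pr, 1L)
  expect_identical(pr[[1]]$anchor_id, "p1")
  expect_null(pr[[1]]$suspect_annotation)

  # same first InChIKey block: structurally unique filter drops the edge
  expect_length(derive_pairs(edge("p1", "p4"), spectra), 0L)
  # no annotation at all
  expect_length(derive_pairs(edge("p3", "p3b"),
                             c(spectra, list(spectrum("p3b", 400, cbind(100, 1))))),
                0L)
  expect_error(derive_pairs(edge("p1", "nope"), spectra), "unknown spectrum")
})
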