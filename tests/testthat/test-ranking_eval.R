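# Average-rank tie handling, site scoring and evaluation metrics.

# bare candidate table for ranking tests (no chemistry involved)
fake_candidates <- function(scores, sites = NULL) {
  n <- length(scores)
  ik <- vapply(seq_len(n), function(i) {
    paste0(paste(rep(LETTERS[(i %% 26) + 1], 14), collapse = ""),
           "-UHFFFAOYSA-N")
  }, character(1))
  df <- data.frame(inchikey = ik, smiles = sprintf("C%d", seq_len(n)),
                   mass = 100 + seq_len(n), score = scores, rank = NA_real_,
                   stringsAsFactors = FALSE)
  prov <- lapply(seq_len(n), function(i) {
    data.frame(rule_id = "r", site_atom = if (is.null(sites)) 0L else sites[i],
               stringsAsFactors = FALSE)
  })
  structure(df, provenance = prov, class = c("bam_candidates", "data.frame"))
}

test_that("three candidates tied for first place all receive average rank 2", {
  cands <- rank_candidates(fake_candidates(c(0.7, 0.7, 0.7)))
  expect_equal(cands$rank, c(2, 2, 2))
})

test_that("distinct scores rank 1..n; leader plus tied pair gives 1, 2.5, 2.5", {
  cands <- rank_candidates(fake_candidates(c(0.2, 0.9, 0.5)))
  expect_equal(sort(cands$rank), c(1, 2, 3))
  expect_equal(cands$score, sort(cands$score, decreasing = TRUE))

  cands <- rank_candidates(fake_candidates(c(0.4, 0.9, 0.4)))
  expect_equal(cands$rank, c(1, 2.5, 2.5))
})

test_that("assigned ranks always sum to n(n+1)/2 and are permutation-invariant", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(1:12, 1)
    scores <- sample(round(stats::runif(5, 0, 1), 1), n, replace = TRUE)
    ranked <- rank_candidates(fake_candidates(scores))
    expect_equal(sum(ranked$rank), n * (n + 1) / 2)
    # permuting the input must not change the rank attached to each identity
    perm <- sample(n)
    ranked2 <- rank_candidates(fake_candidates(scores[perm]))
    key1 <- ranked$rank[order(ranked$score, ranked$inchikey)]
    key2 <- ranked2$rank[order(ranked2$score, ranked2$inchikey)]
    expect_equal(key1, key2)
  }
})

test_that("score_candidates assigns site likelihoods, max over provenances", {
  anchor <- canonicalize("CCO")
  cands <- fake_candidates(c(NA, NA), sites = c(0L, 2L))
  lik <- c(0.1, 0.5, 0.9)
  sc <- site_scorer("fixed", function(mol) lik[seq_len(mol$n_heavy)])
  scored <- score_candidates(anchor, cands, sc)
  expect_equal(scored$score, c(0.1, 0.9))

  # multiple provenances take the maximum over their sites
  multi <- fake_candidates(NA_real_, sites = 0L)
  attr(multi, "provenance") <- list(data.frame(rule_id = c("a", "b"),
                                               site_atom = c(0L, 1L)))
  expect_equal(score_candidates(anchor, multi, sc)$score, 0.5)

  # out-of-range site names the candidate
  bad <- fake_candidates(NA_real_, sites = 7L)
  expect_error(score_candidates(anchor, bad, sc), "site index out of range")
  # scorers returning out-of-contract values are refused
  sc_bad <- site_scorer("bad", function(mol) rep(2, mol$n_heavy))
  expect_error(score_candidates(anchor, cands, sc_bad), "outside")
})

test_that("uniform scorer ties everything; default scorer favors rule centers", {
  anchor <- canonicalize("OC1CCCCC1")
  b <- test_benchmark()
  u <- uniform_site_scorer()$score_atoms(anchor)
  expect_true(all(u == u[1]))
  d <- default_site_scorer(b$table)
  l1 <- d$score_atoms(anchor)
  expect_identical(l1, d$score_atoms(anchor))   # deterministic
  expect_true(all(l1 >= 0 & l1 <= 1))
  # empty table: uniform fallback
  d0 <- default_site_scorer(build_rule_table(NULL))
  expect_true(all(d0$score_atoms(anchor) == 0.5))
})

test_that("evaluation metric arithmetic matches hand-computed values", {
  b <- test_benchmark()
  ev <- evaluate(b$pairs, active_rule_table(b), oracle_site_scorer(b))
  expect_identical(ev$n_queries, length(b$pairs))
  expect_equal(ev$recall, ev$n_correct / ev$n_with_derivatives)
  expect_true(all(diff(ev$rank_at_k) >= 0))   # non-decreasing in k
  expect_gte(ev$average_rank, 1)
  pq <- ev$per_query
  expect_equal(mean(pq$true_rank[pq$correct] <= 1), ev$rank_at_k[["k1"]])
  expect_error(evaluate(list(), b$table, uniform_site_scorer()), "empty")
})

test_that("report serialization is flat and JSON-friendly", {
  b <- test_benchmark()
  ev <- evaluate(b$pairs, active_rule_table(b), uniform_site_scorer())
  s <- evaluation_summary(ev)
  expect_named(s, c("n_queries", "n_with_derivatives", "n_correct", "recall",
                    "rank_at_k", "average_rank", "mean_candidates",
                    "recall_by_tanimoto", "scorer"))
  txt <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA, na = "null")
  expect_true(jsonlite::validate(txt))
})
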