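# Synthetic benchmark generation: toy reaction pairs from a built-in
# transformation catalogue, deterministic pseudo-fragmentation spectra, and
# ground-truthed anchor-suspect benchmarks.  Everything is generated in code
# under a seed; nothing is downloaded.

#' Built-in drug-like / steroid-like scaffold structures
#'
#' About twenty small molecules spanning aromatic, aliphatic, heterocyclic
#' and steroid-like chemistry, shipped as SMILES so tests never download
#' anything.  Stereochemistry is omitted: all identity comparisons downstream
#' use the first InChIKey block (2D connectivity).
#'
#' @return Named character vector of SMILES.
#' @export
bam_scaffolds <- function() {
  c(
    paracetamol   = "CC(=O)Nc1ccc(O)cc1",
    ibuprofen     = "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
    naproxen      = "COc1ccc2cc(C(C)C(=O)O)ccc2c1",
    aspirin       = "CC(=O)Oc1ccccc1C(=O)O",
    caffeine      = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    salbutamol    = "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",
    tyrosine      = "NC(Cc1ccc(O)cc1)C(=O)O",
    tryptophan    = "NC(Cc1c[nH]c2ccccc12)C(=O)O",
    phenylalanine = "NC(Cc1ccccc1)C(=O)O",
    serotonin     = "NCCc1c[nH]c2ccc(O)cc12",
    dopamine      = "NCCc1ccc(O)c(O)c1",
    menthol       = "CC(C)C1CCC(C)CC1O",
    vanillin      = "COc1cc(C=O)ccc1O",
    coumarin      = "O=c1ccc2ccccc2o1",
    quercetin     = "O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12",
    glucose       = "OCC1OC(O)C(O)C(O)C1O",
    citric_acid   = "OC(=O)CC(O)(CC(=O)O)C(=O)O",
    cinnamic_acid = "O=C(O)C=Cc1ccccc1",
    cholate_like  = "CC(CCC(=O)O)C1CCC2C1(C)C(O)CC1C2C(O)CC2CC(O)CCC12C",
    testosterone_like = "CC12CCC(=O)C=C1CCC1C2CCC2(C)C1CCC2O",
    cortisol_like = "CC12CCC(=O)C=C1CCC1C2C(O)CC2(C)C1CCC2(O)C(=O)CO"
  )
}

#' Built-in biotransformation families
#'
#' The toy catalogue used by the fixture generator: each family is a single
#' localized structural change with its monoisotopic mass delta.
#'
#' @return data.frame with columns `family` and `mass_delta` (Da).
#' @export
biotransformation_families <- function() {
  data.frame(
    family = c("hydroxylation", "methylation", "dehydrogenation",
               "demethylation", "acetylation"),
    mass_delta = c(15.9949, 14.0157, -2.0157, -14.0157, 42.0106),
    stringsAsFactors = FALSE)
}

# all legal (site, product) applications for family x scaffold combos,
# one bridge call
family_products <- function(combos) {
  tasks <- lapply(seq_len(nrow(combos)), function(i) {
    list(family = combos$family[i], scaffold = combos$scaffold_smiles[i])
  })
  bridge_call("family_products", list(tasks = tasks))
}

#' Generate reactant-product pairs from the transformation catalogue
#'
#' Applies each named family to each scaffold at one randomly chosen legal
#' site (deterministic under `seed`).  Scaffolds with no legal site for a
#' family are skipped with a log line.
#'
#' @param families Character vector of family names (see
#'   [biotransformation_families()]); defaults to all.
#' @param scaffolds Named character vector of scaffold SMILES; defaults to
#'   [bam_scaffolds()].
#' @param seed Integer seed.
#' @return data.frame with columns `pair_id`, `family`, `scaffold`, `site`
#'   (0-based atom index in the canonical reactant), `reactant_smiles`,
#'   `product_smiles`.
#' @export
make_reaction_pairs <- function(families = biotransformation_families()$family,
                                scaffolds = bam_scaffolds(), seed = 1L) {
  stopifnot(length(scaffolds) == 0L || !is.null(names(scaffolds)))
  if (length(scaffolds) == 0L) {
    return(data.frame(pair_id = character(0), family = character(0),
                      scaffold = character(0), site = integer(0),
                      reactant_smiles = character(0),
                      product_smiles = character(0), stringsAsFactors = FALSE))
  }
  known <- biotransformation_families()$family
  if (!all(families %in% known)) {
    stopf("unknown families: %s", paste(setdiff(families, known), collapse = ", "))
  }
  mols <- molecules(unname(scaffolds))
  combos <- expand.grid(scaffold = names(scaffolds), family = families,
                        stringsAsFactors = FALSE)[, c("family", "scaffold")]
  combos <- combos[order(match(combos$family, families),
                         match(combos$scaffold, names(scaffolds))), ]
  combos$scaffold_smiles <- vapply(mols[scaffolds[combos$scaffold]], `[[`,
                                   character(1), "smiles")
  res <- family_products(combos)
  rows <- list()
  with_seed_local(seed, {
    for (i in seq_len(nrow(combos))) {
      sites <- res[[i]]$sites
      if (!length(sites)) {
        bam_log("fixtures", "no legal %s site on %s; skipped",
                combos$family[i], combos$scaffold[i])
        next
      }
      pick <- sites[[sample.int(length(sites), 1L)]]
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sprintf("%s_%s", combos$family[i], combos$scaffold[i]),
        family = combos$family[i], scaffold = combos$scaffold[i],
        site = as.integer(pick$site),
        reactant_smiles = combos$scaffold_smiles[i],
        product_smiles = pick$product, stringsAsFactors = FALSE)
    }
  })
  if (!length(rows)) {
    return(data.frame(pair_id = character(0), family = character(0),
                      scaffold = character(0), site = integer(0),
                      reactant_smiles = character(0),
                      product_smiles = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# one bridge call for a vector of molecules -> list of peak tables
fragment_batch <- function(smiles) {
  bridge_call("fragment", list(smiles = I(smiles)))
}

build_spectrum_from_fragments <- function(id, frag_rec, annotation = NULL,
                                          adduct = "[M+H]+") {
  shift <- ADDUCT_SHIFTS[[adduct]] %||% ADDUCT_SHIFTS[["[M+H]+"]]
  pm <- frag_rec$precursor_mass + shift
  frags <- frag_rec$fragments
  if (length(frags)) {
    mz <- vapply(frags, function(f) f$mass + shift, numeric(1))
    int <- str_hash01(vapply(frags, `[[`, character(1), "smiles"))
    peaks <- rbind(cbind(mz, int), c(pm, 1))
  } else {
    # no breakable bonds: single peak at the precursor
    peaks <- matrix(c(pm, 1), ncol = 2)
  }
  spectrum(id = id, precursor_mz = pm, peaks = peaks, precursor_charge = 1L,
           adduct = adduct, annotation = annotation)
}

#' Simulate a deterministic pseudo-fragmentation spectrum
#'
#' Fragments are enumerated by breaking each acyclic single bond and
#' hydrogen-capping both pieces; each unique fragment contributes a peak at
#' its `[fragment + H]+` m/z with an intensity given by a deterministic hash
#' of its canonical SMILES (in `(0, 1]`), plus the `[M+H]+` precursor peak at
#' intensity 1.  Molecules differing by one localized modification therefore
#' share unmodified-fragment peaks directly and modified-fragment peaks at
#' the mass shift - exactly the structure that modified cosine rewards.  A
#' molecule with no breakable bond yields the single precursor peak.
#'
#' The generator is a pure function of the structure; `seed` is accepted for
#' interface stability and ignored.
#'
#' @param mol A `bam_molecule` (or SMILES).
#' @param seed Ignored (determinism comes from the structure hash).
#' @param id Spectrum id; defaults to the InChIKey first block.
#' @param annotation Optional annotation to attach (e.g. `mol` itself).
#' @return A `bam_spectrum`.
#' @export
simulate_spectrum <- function(mol, seed = 0L, id = NULL, annotation = NULL) {
  mol <- canonicalize(mol)
  rec <- fragment_batch(mol$smiles)[[1L]]
  if (!isTRUE(rec$ok)) stopf("fragmentation failed for %s", mol$smiles)
  build_spectrum_from_fragments(id %||% inchikey14(mol), rec,
                                annotation = annotation)
}

#' Build a ground-truthed anchor-suspect fixture benchmark
#'
#' Draws (family, scaffold) combinations in seeded random order, applies each
#' transformation at one random legal site, simulates anchor and suspect
#' spectra, and keeps a pair only when (a) the extracted rule regenerates the
#' product from the reactant (first-InChIKey-block match), and (b) the two
#' spectra clear the molecular-network threshold under modified cosine.
#' Combinations failing either check are regenerated from the remaining pool.
#' The rule table is built from all retained pairs (both directions), and a
#' seeded fraction of rules can be withheld to create unexplainable queries.
#'
#' @param n_pairs Number of anchor-suspect pairs (>= 1).
#' @param seed Integer seed; same seed, same benchmark, byte for byte.
#' @param withhold_fraction Fraction of rules to withhold in `[0, 1]`.
#' @param scaffolds,families Catalogue subsets; defaults as in
#'   [make_reaction_pairs()].
#' @param threshold,fragment_tol Network acceptance parameters for the
#'   spectral check (defaults 0.8, 0.02 Da).
#' @return A `bam_benchmark`: `spectra`, `pairs` (each with ground-truth
#'   `suspect_annotation`, `mass_difference`, `edge_score`), `rule_pairs`,
#'   `table` (full rule table), `withheld_rule_ids`, `truth`, `seed`.
#' @export
make_benchmark <- function(n_pairs, seed = 1L, withhold_fraction = 0,
                           scaffolds = bam_scaffolds(),
                           families = biotransformation_families()$family,
                           threshold = 0.8, fragment_tol = 0.02) {
  stopifnot(n_pairs >= 1L, withhold_fraction >= 0, withhold_fraction <= 1)
  all_pairs <- make_reaction_pairs(families = families, scaffolds = scaffolds,
                                   seed = seed)
  if (nrow(all_pairs) == 0L) stopf("no legal transformation on any scaffold")
  ord <- with_seed_local(seed, sample.int(nrow(all_pairs)))
  all_pairs <- all_pairs[ord, , drop = FALSE]

  # round-trip check, one extraction + one application call for the pool
  res <- extract_rules_batch(all_pairs, min_mcs_frac = 0.5)
  mols <- molecules(unique(c(all_pairs$reactant_smiles,
                             all_pairs$product_smiles)))
  tasks <- lapply(all_pairs$pair_id, function(pid) {
    list(anchor = mols[[all_pairs$reactant_smiles[match(pid, all_pairs$pair_id)]]],
         rules = res$rules[[pid]] %||% list())
  })
  cand <- apply_rules_batch(tasks)
  roundtrip_ok <- vapply(seq_len(nrow(all_pairs)), function(i) {
    truth14 <- inchikey14(mols[[all_pairs$product_smiles[i]]])
    any(substr(cand[[i]]$inchikey, 1, 14) == truth14)
  }, logical(1))
  distinct <- vapply(seq_len(nrow(all_pairs)), function(i) {
    !identical(inchikey14(mols[[all_pairs$reactant_smiles[i]]]),
               inchikey14(mols[[all_pairs$product_smiles[i]]]))
  }, logical(1))

  # spectral check
  frag_smiles <- unique(c(all_pairs$reactant_smiles, all_pairs$product_smiles))
  frecs <- stats::setNames(fragment_batch(frag_smiles), frag_smiles)
  kept <- list()
  spectra <- list()
  pairs <- list()
  for (i in seq_len(nrow(all_pairs))) {
    if (length(kept) >= n_pairs) break
    if (!roundtrip_ok[i] || !distinct[i]) {
      bam_log("fixtures", "pair %s regenerated (%s)", all_pairs$pair_id[i],
              if (!distinct[i]) "reactant and product share 2D structure"
              else "rule round-trip failed")
      next
    }
    pid <- all_pairs$pair_id[i]
    anchor_mol <- mols[[all_pairs$reactant_smiles[i]]]
    suspect_mol <- mols[[all_pairs$product_smiles[i]]]
    sa <- build_spectrum_from_fragments(paste0("A_", pid),
                                        frecs[[all_pairs$reactant_smiles[i]]],
                                        annotation = anchor_mol)
    ss <- build_spectrum_from_fragments(paste0("S_", pid),
                                        frecs[[all_pairs$product_smiles[i]]],
                                        annotation = suspect_mol)
    mc <- modified_cosine(sa, ss, fragment_tol = fragment_tol)
    if (!(mc$score > threshold)) {
      bam_log("fixtures", "pair %s regenerated (modified cosine %.3f <= %.2f)",
              pid, mc$score, threshold)
      next
    }
    kept[[length(kept) + 1L]] <- all_pairs[i, , drop = FALSE]
    spectra <- c(spectra, list(sa, ss))
    pairs[[length(pairs) + 1L]] <- structure(list(
      anchor_id = sa$id, suspect_id = ss$id, anchor = anchor_mol,
      suspect_annotation = suspect_mol,
      mass_difference = neutral_mass(ss) - neutral_mass(sa),
      edge_score = mc$score, pair_id = pid,
      true_site = all_pairs$site[i], family = all_pairs$family[i]),
      class = "bam_pair")
  }
  if (length(kept) < n_pairs) {
    warning(sprintf("benchmark holds %d of the requested %d pairs (pool exhausted)",
                    length(kept), n_pairs))
  }
  rule_pairs <- do.call(rbind, kept)
  rownames(rule_pairs) <- NULL
  table <- build_rule_table(rule_pairs[, c("pair_id", "reactant_smiles",
                                           "product_smiles")], verbose = FALSE)
  withheld <- character(0)
  if (withhold_fraction > 0 && length(table$rules)) {
    n_hold <- ceiling(withhold_fraction * length(table$rules))
    withheld <- with_seed_local(seed + 1L, {
      sort(sample(names(table$rules), n_hold))
    })
  }
  truth <- data.frame(
    pair_id = rule_pairs$pair_id,
    anchor_id = paste0("A_", rule_pairs$pair_id),
    suspect_id = paste0("S_", rule_pairs$pair_id),
    family = rule_pairs$family,
    site = rule_pairs$site,
    suspect_smiles = rule_pairs$product_smiles,
    stringsAsFactors = FALSE)
  structure(
    list(spectra = spectra, pairs = pairs, rule_pairs = rule_pairs,
         table = table, withheld_rule_ids = withheld, truth = truth,
         seed = as.integer(seed)),
    class = "bam_benchmark")
}

#' @export
print.bam_benchmark <- function(x, ...) {
  cat(sprintf("<bam_benchmark> %d pair(s), %d spectra, %d rule(s) (%d withheld), seed %d\n",
              length(x$pairs), length(x$spectra), length(x$table$rules),
              length(x$withheld_rule_ids), x$seed))
  invisible(x)
}

#' Rule table of a benchmark with withheld rules removed
#'
#' @param benchmark A `bam_benchmark`.
#' @return A `bam_rule_table`.
#' @export
active_rule_table <- function(benchmark) {
  stopifnot(inherits(benchmark, "bam_benchmark"))
  withhold_rules(benchmark$table, benchmark$withheld_rule_ids)
}

#' Oracle site scorer for a fixture benchmark
#'
#' Knows the true reaction-center site of every benchmark query: likelihood 1
#' at the true site, 0 elsewhere.  Because one anchor can serve several
#' queries (different transformations of the same scaffold), the oracle is
#' query-aware: it carries a `for_pair` hook that [evaluate()] uses to bind
#' the scorer to the current anchor-suspect pair (keyed on the two first
#' InChIKey blocks).  Used to test that the ranking machinery places a
#' correctly generated truth first; it is not a model of chemistry.
#'
#' @param benchmark A `bam_benchmark`.
#' @return A `bam_site_scorer` with a `for_pair` field.
#' @export
oracle_site_scorer <- function(benchmark) {
  stopifnot(inherits(benchmark, "bam_benchmark"))
  site_by_query <- list()
  for (p in benchmark$pairs) {
    key <- paste(inchikey14(p$anchor), inchikey14(p$suspect_annotation))
    site_by_query[[key]] <- p$true_site
  }
  sc <- site_scorer("oracle", function(mol) rep(0, mol$n_heavy))
  sc$for_pair <- function(pair) {
    key <- if (!is.null(pair$suspect_annotation)) {
      paste(inchikey14(pair$anchor), inchikey14(pair$suspect_annotation))
    } else ""
    s <- site_by_query[[key]]
    function(mol) {
      lik <- rep(0, mol$n_heavy)
      if (!is.null(s) && s < mol$n_heavy) lik[s + 1L] <- 1
      lik
    }
  }
  sc
}

#' Write a benchmark to disk as plain-text fixture files
#'
#' Writes `spectra.mgf` (anchors and suspects, both annotated; suspect
#' annotations are the ground truth, which the pipeline only uses for
#' evaluation), `rules.json`, `rule_pairs.tsv`, `pairs.tsv`, `truth.tsv`
#' and `withheld_rules.txt`.
#'
#' @param benchmark A `bam_benchmark`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "bam_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mgf(benchmark$spectra, file.path(dir, "spectra.mgf"))
  write_rule_table(benchmark$table, file.path(dir, "rules.json"))
  utils::write.table(benchmark$rule_pairs[, c("pair_id", "reactant_smiles",
                                              "product_smiles")],
                     file.path(dir, "rule_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pairs_df <- do.call(rbind, lapply(benchmark$pairs, function(p) {
    data.frame(anchor_id = p$anchor_id, suspect_id = p$suspect_id,
               mass_difference = p$mass_difference,
               edge_score = p$edge_score, stringsAsFactors = FALSE)
  }))
  utils::write.table(pairs_df, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(benchmark$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(benchmark$withheld_rule_ids, file.path(dir, "withheld_rules.txt"))
  invisible(dir)
}
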