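# Biotransformation rule extraction (PROXIMAL2-style) and the mass-delta
# indexed rule table (pipeline step 2, first half).
#
# A rule is one connected reaction center: reactant and product are aligned
# by maximum common substructure; atoms outside the MCS and MCS atoms whose
# bonding differs delimit the center.  The rule carries the center atom-type
# code, the multiset of its bonded-neighbor codes, a serialized structural
# edit (add / remove a neighbor subtree, change a center-neighbor bond order)
# and the realized monoisotopic mass delta.  Atom-type codes approximate KEGG
# atom types with element + aromatic/ring/chain class + sorted
# neighbor-element-with-bond-order profile; the scheme only needs to be
# self-consistent between extraction and application.

new_rule <- function(rec, id, source_reactant = NA_character_,
                     source_product = NA_character_) {
  structure(
    list(
      id = id,
      source_pair = c(reactant = source_reactant, product = source_product),
      center_code = rec$center_code,
      neighbor_codes = sort(as.character(unlist(rec$neighbor_codes))),
      ops = rec$ops,
      mass_delta = rec$mass_delta
    ),
    class = "bam_rule"
  )
}

is_rule <- function(x) inherits(x, "bam_rule")

#' @export
print.bam_rule <- function(x, ...) {
  cat(sprintf("<bam_rule> %s  delta %+.4f Da\n  center %s  neighbors [%s]\n  edit: %s\n",
              x$id, x$mass_delta, x$center_code,
              paste(x$neighbor_codes, collapse = ", "), edit_signature(x)))
  invisible(x)
}

# canonical serialization of the structural edit; also the dedup key component
edit_signature <- function(rule) {
  ops <- lapply(rule$ops, function(o) o[order(names(o))])
  paste(vapply(ops, function(o) {
    paste(names(o), unlist(o), sep = "=", collapse = ",")
  }, character(1)), collapse = " | ")
}

rule_identity <- function(rule) {
  paste(rule$center_code,
        paste(rule$neighbor_codes, collapse = ";"),
        edit_signature(rule), sep = " :: ")
}

#' Extract biotransformation rules from one reactant-product pair
#'
#' Aligns the two structures with a bond-order-sensitive, ring-matches-ring
#' maximum common substructure, delimits the reaction center(s), and emits
#' one rule per connected center.  Identical molecules, pairs whose MCS
#' covers less than `min_mcs_frac` of the smaller molecule's heavy atoms,
#' and changes not expressible at a single center yield an empty list with
#' the reason attached as the `"reason"` attribute.
#'
#' @param reactant,product `bam_molecule` objects or SMILES strings.
#' @param min_mcs_frac Minimum fraction of the smaller molecule's heavy atoms
#'   the MCS must cover (default 0.5; below it the alignment is deemed
#'   unreliable).
#' @param timeout MCS search timeout in seconds per pair (default 10).
#' @return List of `bam_rule`.
#' @export
extract_rules <- function(reactant, product, min_mcs_frac = 0.5, timeout = 10) {
  reactant <- canonicalize(reactant)
  product <- canonicalize(product)
  res <- extract_rules_batch(
    data.frame(pair_id = "pair", reactant_smiles = reactant$smiles,
               product_smiles = product$smiles, stringsAsFactors = FALSE),
    min_mcs_frac = min_mcs_frac, timeout = timeout)
  rules <- res$rules[["pair"]] %||% list()
  attr(rules, "reason") <- res$reasons[["pair"]]
  rules
}

# batched extraction: one bridge call for a whole pair table
extract_rules_batch <- function(pairs, min_mcs_frac = 0.5, timeout = 10) {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "reactant_smiles", "product_smiles") %in% names(pairs)))
  tasks <- lapply(seq_len(nrow(pairs)), function(i) {
    list(reactant = pairs$reactant_smiles[i], product = pairs$product_smiles[i])
  })
  res <- bridge_call("extract_rules",
                     list(pairs = tasks, min_mcs_frac = min_mcs_frac,
                          timeout = timeout))
  rules <- list()
  reasons <- list()
  for (i in seq_along(res)) {
    pid <- pairs$pair_id[i]
    rl <- res[[i]]$rules
    rules[[pid]] <- lapply(seq_along(rl), function(j) {
      new_rule(rl[[j]], id = sprintf("%s.%d", pid, j),
               source_reactant = pairs$reactant_smiles[i],
               source_product = pairs$product_smiles[i])
    })
    reasons[[pid]] <- res[[i]]$skipped_reason
  }
  list(rules = rules, reasons = reasons)
}

#' Build a mass-delta indexed rule table from reactant-product pairs
#'
#' Extracts rules from every pair in both reaction directions (each pair also
#' contributes the reverse rule with negated delta, honoring reversibility),
#' de-duplicates on (center code, neighbor codes, edit), and indexes the
#' survivors by unit-rounded mass delta (round half away from zero).
#' Unparseable or unalignable pairs are logged and skipped.
#'
#' @param pairs data.frame with columns `pair_id`, `reactant_smiles`,
#'   `product_smiles`.
#' @param min_mcs_frac,timeout Passed to the extractor.
#' @param verbose Log skipped pairs; default `TRUE`.
#' @return A `bam_rule_table` with elements `rules` (named list) and `index`
#'   (map from integer-Da delta, as character, to rule ids).
#' @export
build_rule_table <- function(pairs, min_mcs_frac = 0.5, timeout = 10,
                             verbose = TRUE) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(new_rule_table(list()))
  }
  # validate/canonicalize structures first; drop unparseable pairs
  all_smiles <- unique(c(pairs$reactant_smiles, pairs$product_smiles))
  mols <- molecules(all_smiles, on_error = "skip")
  ok <- pairs$reactant_smiles %in% names(mols) &
    pairs$product_smiles %in% names(mols)
  if (any(!ok) && verbose) {
    bam_log("rules", "skipping %d unparseable pair(s)", sum(!ok))
  }
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) return(new_rule_table(list()))
  fwd <- data.frame(
    pair_id = paste0(pairs$pair_id, ".fwd"),
    reactant_smiles = vapply(mols[pairs$reactant_smiles], `[[`, character(1), "smiles"),
    product_smiles = vapply(mols[pairs$product_smiles], `[[`, character(1), "smiles"),
    stringsAsFactors = FALSE)
  rev <- data.frame(
    pair_id = paste0(pairs$pair_id, ".rev"),
    reactant_smiles = fwd$product_smiles,
    product_smiles = fwd$reactant_smiles,
    stringsAsFactors = FALSE)
  res <- extract_rules_batch(rbind(fwd, rev), min_mcs_frac = min_mcs_frac,
                             timeout = timeout)
  rules <- list()
  seen <- character(0)
  for (pid in names(res$rules)) {
    if (!length(res$rules[[pid]]) && !is.null(res$reasons[[pid]]) && verbose) {
      bam_log("rules", "pair %s produced no rule: %s", pid, res$reasons[[pid]])
    }
    for (r in res$rules[[pid]]) {
      key <- rule_identity(r)
      if (key %in% seen) next
      seen <- c(seen, key)
      rules[[r$id]] <- r
    }
  }
  new_rule_table(rules)
}

new_rule_table <- function(rules) {
  index <- list()
  for (r in rules) {
    key <- as.character(round_half_away(r$mass_delta))
    index[[key]] <- c(index[[key]], r$id)
  }
  structure(list(rules = rules, index = index), class = "bam_rule_table")
}

is_rule_table <- function(x) inherits(x, "bam_rule_table")

#' @export
print.bam_rule_table <- function(x, ...) {
  cat(sprintf("<bam_rule_table> %d rule(s), %d mass-delta key(s): %s\n",
              length(x$rules), length(x$index),
              paste(sort(as.integer(names(x$index))), collapse = ", ")))
  invisible(x)
}

#' Look up rules matching an observed mass difference
#'
#' Returns the rules whose unit-rounded mass delta equals the unit-rounded
#' observed difference (round half away from zero).  An empty list is a legal
#' outcome: some anchor-suspect pairs cannot be explained by any rule.
#'
#' @param table A `bam_rule_table`.
#' @param observed_mass_difference Observed neutral-mass difference in Da.
#' @return List of `bam_rule`.
#' @export
match_rules <- function(table, observed_mass_difference) {
  stopifnot(is_rule_table(table))
  key <- as.character(round_half_away(observed_mass_difference))
  ids <- table$index[[key]]
  if (is.null(ids)) return(list())
  unname(table$rules[ids])
}

#' Remove rules from a table (e.g. fixture withholding)
#'
#' @param table A `bam_rule_table`.
#' @param rule_ids Character vector of rule ids to drop.
#' @return A new `bam_rule_table` without those rules, re-indexed.
#' @export
withhold_rules <- function(table, rule_ids) {
  stopifnot(is_rule_table(table))
  keep <- setdiff(names(table$rules), rule_ids)
  new_rule_table(table$rules[keep])
}

RULE_TABLE_FORMAT <- 1L

#' Serialize a rule table to versioned JSON
#'
#' Schema: `{"format_version": 1, "rules": [{"id", "source_pair",
#' "center_code", "neighbor_codes", "ops", "mass_delta"}, ...]}`; the
#' mass-delta index is rebuilt on load.
#'
#' @param table A `bam_rule_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rule_table <- function(table, path) {
  stopifnot(is_rule_table(table))
  recs <- lapply(unname(table$rules), function(r) {
    list(id = r$id,
         source_pair = as.list(r$source_pair),
         center_code = r$center_code,
         neighbor_codes = I(r$neighbor_codes),
         ops = r$ops,
         mass_delta = r$mass_delta)
  })
  jsonlite::write_json(list(format_version = RULE_TABLE_FORMAT, rules = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rule table written by [write_rule_table()]
#'
#' @param path JSON file path.
#' @return A `bam_rule_table`.
#' @export
read_rule_table <- function(path) {
  if (!file.exists(path)) stopf("rule table not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(as.integer(doc$format_version %||% -1L), RULE_TABLE_FORMAT)) {
    stopf("unsupported rule table format_version: %s",
          doc$format_version %||% "missing")
  }
  rules <- list()
  for (rec in doc$rules) {
    r <- new_rule(rec, id = rec$id,
                  source_reactant = rec$source_pair$reactant %||% NA_character_,
                  source_product = rec$source_pair$product %||% NA_character_)
    rules[[r$id]] <- r
  }
  new_rule_table(rules)
}
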