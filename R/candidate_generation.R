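# Candidate suspect enumeration: apply mass-matched rules to an anchor at
# every compatible site (pipeline step 2, second half).
#
# A site is compatible when the anchor atom's type code equals the rule's
# center code AND the full multiset of its bonded-neighbor codes equals the
# rule's neighborhood (subset matching would inflate candidates; a
# lookup-table scheme implies the exact local environment).  Products that
# fail valence/aromaticity sanitization or yield no standard InChI are
# discarded; survivors are de-duplicated on the first InChIKey block,
# retaining every (rule_id, site_atom) provenance.

empty_candidates <- function() {
  structure(
    data.frame(inchikey = character(0), smiles = character(0),
               mass = numeric(0), score = numeric(0), rank = numeric(0),
               stringsAsFactors = FALSE),
    provenance = list(), class = c("bam_candidates", "data.frame"))
}

# assemble a candidate table from raw bridge hits, de-duplicating on the
# first InChIKey block and merging provenance
assemble_candidates <- function(hits) {
  if (!length(hits)) return(empty_candidates())
  ik <- vapply(hits, `[[`, character(1), "inchikey")
  ik14 <- substr(ik, 1L, 14L)
  ord <- order(ik, vapply(hits, `[[`, character(1), "rule_id"),
               vapply(hits, function(h) h$site_atom, numeric(1)))
  hits <- hits[ord]
  ik <- ik[ord]
  ik14 <- ik14[ord]
  first <- !duplicated(ik14)
  rows <- data.frame(
    inchikey = ik[first],
    smiles = vapply(hits[first], `[[`, character(1), "smiles"),
    mass = vapply(hits[first], `[[`, numeric(1), "mass"),
    score = NA_real_, rank = NA_real_, stringsAsFactors = FALSE)
  prov <- lapply(ik14[first], function(key) {
    sel <- hits[ik14 == key]
    unique(data.frame(
      rule_id = vapply(sel, `[[`, character(1), "rule_id"),
      site_atom = as.integer(vapply(sel, function(h) h$site_atom, numeric(1))),
      stringsAsFactors = FALSE))
  })
  structure(rows, provenance = prov, class = c("bam_candidates", "data.frame"))
}

#' Candidate provenance records
#'
#' @param candidates A `bam_candidates` table.
#' @return List (one element per candidate row) of data.frames with columns
#'   `rule_id` and `site_atom` (0-based anchor heavy-atom index).
#' @export
candidate_provenance <- function(candidates) {
  attr(candidates, "provenance")
}

#' @export
print.bam_candidates <- function(x, ...) {
  cat(sprintf("<bam_candidates> %d candidate(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- data.frame(inchikey14 = substr(x$inchikey, 1, 14),
                       smiles = x$smiles, mass = round(x$mass, 4),
                       score = round(x$score, 4), rank = x$rank)
    print.data.frame(utils::head(show, 10))
    if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  }
  invisible(x)
}

# serialize rules for the bridge (neighbor_codes / ops must stay JSON arrays)
rules_payload <- function(rules) {
  lapply(rules, function(r) {
    list(id = r$id, center_code = r$center_code,
         neighbor_codes = I(r$neighbor_codes), ops = r$ops)
  })
}

# batched application: tasks = list of list(anchor = bam_molecule, rules = list)
apply_rules_batch <- function(tasks, max_sites = 64L) {
  nonempty <- which(vapply(tasks, function(t) length(t$rules) > 0, logical(1)))
  out <- rep(list(empty_candidates()), length(tasks))
  if (!length(nonempty)) return(out)
  payload <- lapply(tasks[nonempty], function(t) {
    list(anchor = t$anchor$smiles, rules = rules_payload(t$rules))
  })
  res <- bridge_call("apply_rules", list(tasks = payload, max_sites = max_sites))
  for (k in seq_along(nonempty)) {
    r <- res[[k]]
    if (!isTRUE(r$ok)) {
      stopf("rule application failed: %s", r$message %||% "unknown")
    }
    if (isTRUE(r$site_cap_hit)) {
      bam_log("candidates", "site enumeration cap (%d) hit for anchor %s",
              max_sites, tasks[[nonempty[k]]]$anchor$smiles)
    }
    out[[nonempty[k]]] <- assemble_candidates(r$candidates)
  }
  out
}

#' Apply one biotransformation rule to an anchor structure
#'
#' Every anchor atom whose type code and bonded-neighborhood codes match the
#' rule's center/neighborhood receives the structural edit.  Chemically
#' invalid products are discarded; results are de-duplicated on the first
#' InChIKey block (symmetric sites collapse), with the surviving site(s)
#' recorded as provenance.  Per rule, site enumeration is capped at
#' `max_sites` (logged when hit).
#'
#' @param anchor A `bam_molecule` (or SMILES).
#' @param rule A `bam_rule`.
#' @param max_sites Site-enumeration cap; default 64.
#' @return A `bam_candidates` table (possibly empty).
#' @export
apply_rule <- function(anchor, rule, max_sites = 64L) {
  anchor <- canonicalize(anchor)
  stopifnot(is_rule(rule))
  apply_rules_batch(list(list(anchor = anchor, rules = list(rule))),
                    max_sites = max_sites)[[1L]]
}

#' Generate candidate suspect structures for an anchor-suspect pair
#'
#' Looks up the rules whose unit-rounded mass delta matches the pair's
#' observed mass difference and applies each to the anchor at every
#' compatible site.  Candidates are de-duplicated across rules on the first
#' InChIKey block, retaining every (rule_id, site_atom) provenance; row
#' order is deterministic (ascending InChIKey).  An empty result is legal
#' and means "no derivative generated".
#'
#' @param pair A `bam_pair` (anchor annotation required).
#' @param table A `bam_rule_table`.
#' @param max_sites Per-rule site cap; default 64.
#' @return A `bam_candidates` table.
#' @export
generate_candidates <- function(pair, table, max_sites = 64L) {
  stopifnot(inherits(pair, "bam_pair"))
  if (is.null(pair$anchor)) stopf("pair has no annotated anchor")
  rules <- match_rules(table, pair$mass_difference)
  apply_rules_batch(list(list(anchor = pair$anchor, rules = rules)),
                    max_sites = max_sites)[[1L]]
}
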