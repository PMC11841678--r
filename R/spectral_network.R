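# Modified cosine similarity, molecular-network construction and
# anchor-suspect pair derivation (pipeline step 1).
#
# Peak pairing is solved exactly as a maximum-weight bipartite matching over
# the candidate (direct + shifted) peak pairs, weight = product of the
# sqrt-transformed, L2-normalized intensities.  Greedy assignment is not used:
# ties and overlapping candidates change the score.

#' Modified cosine similarity between two spectra
#'
#' Peaks of `a` may pair with peaks of `b` either directly
#' (`|mz_a - mz_b| <= fragment_tol`) or shifted by the neutral precursor mass
#' difference (`|mz_a + delta - mz_b| <= fragment_tol`, with
#' `delta = neutral(b) - neutral(a)`).  Each peak is used at most once; the
#' score is the cosine of the matched intensity products maximized over all
#' one-to-one pairings, and is symmetric in its arguments.
#'
#' @param a,b `bam_spectrum` objects.
#' @param fragment_tol Fragment m/z tolerance in Da (> 0); default 0.02.
#' @param sqrt_intensity Square-root transform intensities before
#'   L2-normalization (the molecular-networking convention); `TRUE` by default.
#' @return List with `score` in `[0, 1]` and `n_matched_peaks`.
#' @export
modified_cosine <- function(a, b, fragment_tol = 0.02, sqrt_intensity = TRUE) {
  stopifnot(is_spectrum(a), is_spectrum(b))
  if (!isTRUE(fragment_tol > 0)) stopf("fragment_tol must be > 0")
  wa <- peak_weights(a, sqrt_intensity)
  wb <- peak_weights(b, sqrt_intensity)
  mza <- a$peaks[, "mz"]
  mzb <- b$peaks[, "mz"]
  delta <- neutral_mass(b) - neutral_mass(a)
  direct <- abs(outer(mza, mzb, "-")) <= fragment_tol
  shifted <- abs(outer(mza + delta, mzb, "-")) <= fragment_tol
  cand <- which(direct | shifted, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(list(score = 0, n_matched_peaks = 0L))
  na <- length(mza)
  w <- wa[cand[, 1L]] * wb[cand[, 2L]]
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, na), rep(TRUE, length(mzb))),
    edges = as.vector(rbind(cand[, 1L], na + cand[, 2L])),
    directed = FALSE)
  m <- igraph::max_bipartite_match(g, weights = w, eps = 1e-12)
  score <- min(1, max(0, m$matching_weight))
  list(score = score, n_matched_peaks = as.integer(m$matching_size))
}

peak_weights <- function(s, sqrt_intensity) {
  w <- s$peaks[, "intensity"]
  if (sqrt_intensity) w <- sqrt(w)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) return(w)
  w / nrm
}

#' Build a molecular network from spectra
#'
#' Computes the modified cosine for every unordered spectrum pair and keeps
#' the edges strictly above `threshold`.  The result is invariant to the
#' input order (edges are reported with the lexicographically smaller id
#' first and sorted).
#'
#' @param spectra List of `bam_spectrum` with unique ids.
#' @param threshold Similarity threshold in `(0, 1]`; edges must exceed it
#'   strictly.  Default 0.8.
#' @param fragment_tol Fragment tolerance in Da; default 0.02.
#' @param sqrt_intensity Passed to [modified_cosine()].
#' @return data.frame with columns `spectrum_id_a`, `spectrum_id_b`, `score`,
#'   `n_matched_peaks`.
#' @export
build_network <- function(spectra, threshold = 0.8, fragment_tol = 0.02,
                          sqrt_intensity = TRUE) {
  if (!isTRUE(threshold > 0 && threshold <= 1)) {
    stopf("threshold must be in (0, 1]")
  }
  empty <- data.frame(spectrum_id_a = character(0), spectrum_id_b = character(0),
                      score = numeric(0), n_matched_peaks = integer(0),
                      stringsAsFactors = FALSE)
  if (length(spectra) < 2L) return(empty)
  ids <- vapply(spectra, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stopf("duplicate spectrum ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order(ids)
  spectra <- spectra[ord]
  ids <- ids[ord]
  rows <- list()
  n <- length(spectra)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      mc <- modified_cosine(spectra[[i]], spectra[[j]],
                            fragment_tol = fragment_tol,
                            sqrt_intensity = sqrt_intensity)
      if (mc$score > threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          spectrum_id_a = ids[i], spectrum_id_b = ids[j],
          score = mc$score, n_matched_peaks = mc$n_matched_peaks,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$spectrum_id_a, out$spectrum_id_b), , drop = FALSE]
}

#' Derive directed anchor-suspect pairs from network edges
#'
#' Biotransformations are reversible, so an edge between two annotated,
#' structurally distinct spectra yields two directed pairs (each compound in
#' turn serving as anchor).  An edge with exactly one annotated endpoint
#' yields one pair (the annotated node is the anchor).  Edges between spectra
#' whose annotations share the first InChIKey block (same 2D structure) or
#' with two unannotated endpoints yield none.
#'
#' @param edges data.frame from [build_network()].
#' @param spectra List of `bam_spectrum`; every edge endpoint must be present.
#' @return List of `bam_pair`: `anchor_id`, `suspect_id`, `anchor`
#'   (annotation of the anchor spectrum), `suspect_annotation` (ground truth
#'   if the suspect is annotated, else `NULL`), `mass_difference` (suspect
#'   neutral mass minus anchor neutral mass, Da) and `edge_score`.
#' @export
derive_pairs <- function(edges, spectra) {
  ids <- vapply(spectra, `[[`, character(1), "id")
  index <- stats::setNames(spectra, ids)
  out <- list()
  for (k in seq_len(nrow(edges))) {
    ia <- edges$spectrum_id_a[k]
    ib <- edges$spectrum_id_b[k]
    if (is.null(index[[ia]]) || is.null(index[[ib]])) {
      stopf("edge %d references unknown spectrum id '%s'", k,
            if (is.null(index[[ia]])) ia else ib)
    }
    sa <- index[[ia]]
    sb <- index[[ib]]
    ann_a <- sa$annotation
    ann_b <- sb$annotation
    if (is.null(ann_a) && is.null(ann_b)) next
    if (!is.null(ann_a) && !is.null(ann_b) && inchikey14_match(ann_a, ann_b)) next
    mk <- function(anchor_sp, suspect_sp) {
      structure(list(
        anchor_id = anchor_sp$id,
        suspect_id = suspect_sp$id,
        anchor = anchor_sp$annotation,
        suspect_annotation = suspect_sp$annotation,
        mass_difference = neutral_mass(suspect_sp) - neutral_mass(anchor_sp),
        edge_score = edges$score[k]), class = "bam_pair")
    }
    if (!is.null(ann_a)) out[[length(out) + 1L]] <- mk(sa, sb)
    if (!is.null(ann_b)) out[[length(out) + 1L]] <- mk(sb, sa)
  }
  out
}

#' @export
print.bam_pair <- function(x, ...) {
  cat(sprintf("<bam_pair> anchor %s -> suspect %s  (delta %+.4f Da, edge %.3f)\n",
              x$anchor_id, x$suspect_id, x$mass_difference, x$edge_score))
  invisible(x)
}

#' Write network edges as TSV
#' @param edges data.frame from [build_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write network as GraphML
#' @param edges data.frame from [build_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(edges, path) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
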