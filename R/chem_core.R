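# Molecular identity, mass and similarity primitives.
#
# A `bam_molecule` carries the canonical SMILES, the standard InChIKey, the
# monoisotopic mass, a Morgan fingerprint (radius 2, 2048 bits; stored as the
# sorted indices of the on bits) and per-heavy-atom type codes.  Atom indices
# used everywhere downstream (reaction-center sites, scorer likelihoods) are
# 0-based positions in the canonical SMILES heavy-atom order.

FP_RADIUS <- 2L
FP_NBITS <- 2048L

new_molecule <- function(rec) {
  structure(
    list(
      smiles = rec$canonical_smiles,
      inchikey = rec$inchikey,
      monoisotopic_mass = rec$monoisotopic_mass,
      formula = rec$formula,
      n_heavy = as.integer(rec$n_heavy),
      fingerprint = as.integer(unlist(rec$fp_bits)),
      fp_meta = c(radius = FP_RADIUS, nbits = FP_NBITS),
      atom_codes = as.character(unlist(rec$atom_codes))
    ),
    class = "bam_molecule"
  )
}

#' Canonicalize a structure into a molecule object
#'
#' Parses a SMILES string and returns a `bam_molecule` with the canonical
#' SMILES, standard InChIKey, monoisotopic mass, molecular formula, Morgan
#' fingerprint and per-atom type codes populated.  Different notations of the
#' same connectivity give identical canonical molecules.
#'
#' @param structure_text A SMILES string (a `bam_molecule` is returned
#'   unchanged).
#' @return A `bam_molecule`.
#' @seealso [molecules()] for the vectorized form, [inchikey14_match()],
#'   [tanimoto()].
#' @export
#' @examples
#' \dontrun{
#' m <- canonicalize("OCC")
#' m$smiles            # "CCO"
#' m$monoisotopic_mass # 46.0419
#' }
canonicalize <- function(structure_text) {
  if (inherits(structure_text, "bam_molecule")) return(structure_text)
  stopifnot(is.character(structure_text), length(structure_text) == 1L)
  molecules(structure_text)[[1L]]
}

#' Canonicalize a vector of SMILES in one bridge call
#'
#' @param smiles Character vector of SMILES strings.
#' @param on_error `"stop"` (default) raises a classed condition
#'   (`bam_parse_error` or `bam_valence_error`) naming the offending text;
#'   `"skip"` drops failing entries with a warning.
#' @return A named list of `bam_molecule` (names are the input strings).
#' @export
molecules <- function(smiles, on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(list())
  if (is.null(.bam$mol_cache)) .bam$mol_cache <- new.env(parent = emptyenv())
  res <- vector("list", length(smiles))
  names(res) <- smiles
  todo <- character(0)
  for (s in unique(smiles)) {
    if (is.null(.bam$mol_cache[[s]])) todo <- c(todo, s)
  }
  if (length(todo)) {
    recs <- bridge_call("canonicalize", list(smiles = I(todo)))
    for (i in seq_along(todo)) .bam$mol_cache[[todo[i]]] <- recs[[i]]
  }
  keep <- rep(TRUE, length(smiles))
  for (i in seq_along(smiles)) {
    rec <- .bam$mol_cache[[smiles[i]]]
    if (isTRUE(rec$ok)) {
      res[[i]] <- new_molecule(rec)
    } else if (on_error == "stop") {
      cls <- if (identical(rec$error_type, "parse")) "bam_parse_error"
             else "bam_valence_error"
      stopf("invalid structure %s: %s", shQuote(smiles[i]),
            rec$message %||% "unknown", class = cls)
    } else {
      warning(sprintf("skipping invalid structure %s", shQuote(smiles[i])))
      keep[i] <- FALSE
    }
  }
  res[keep]
}

is_molecule <- function(x) inherits(x, "bam_molecule")

#' @export
print.bam_molecule <- function(x, ...) {
  cat(sprintf("<bam_molecule> %s\n  InChIKey: %s  mass: %.4f Da  (%s, %d heavy atoms)\n",
              x$smiles, x$inchikey, x$monoisotopic_mass, x$formula, x$n_heavy))
  invisible(x)
}

#' First InChIKey block (2D connectivity hash)
#'
#' @param x A `bam_molecule` or an InChIKey string.
#' @return The first 14 characters of the standard InChIKey.
#' @export
inchikey14 <- function(x) {
  key <- if (is_molecule(x)) x$inchikey else as.character(x)
  substr(key, 1L, 14L)
}

#' Compare two molecules on the first InChIKey block
#'
#' Identity criterion for 2D structures: stereochemistry and protonation
#' differences live in the later InChIKey blocks and do not affect the result.
#'
#' @param a,b `bam_molecule` objects.
#' @return `TRUE` iff the first 14 InChIKey characters agree.
#' @export
inchikey14_match <- function(a, b) {
  stopifnot(is_molecule(a), is_molecule(b))
  identical(inchikey14(a), inchikey14(b))
}

#' Tanimoto similarity of Morgan fingerprints
#'
#' Jaccard index of the fingerprint on-bit sets: `|A & B| / |A | B|`.
#' Both molecules must carry fingerprints computed with identical parameters
#' (radius 2, 2048 bits throughout this package).
#'
#' @param a,b `bam_molecule` objects.
#' @return Similarity in `[0, 1]`; 1 for identical molecules.
#' @export
tanimoto <- function(a, b) {
  stopifnot(is_molecule(a), is_molecule(b))
  if (!identical(a$fp_meta, b$fp_meta)) {
    stopf("fingerprint parameter mismatch", class = "bam_fp_error")
  }
  n_and <- length(intersect(a$fingerprint, b$fingerprint))
  n_or <- length(union(a$fingerprint, b$fingerprint))
  if (n_or == 0L) return(0)
  n_and / n_or
}

#' Validate the structural invariants of a molecule object
#'
#' Checks the InChIKey layout (hyphens at positions 15 and 26, 14-character
#' first block) and a positive monoisotopic mass.  Called by constructors;
#' exported for defensive use on deserialized objects.
#'
#' @param x A `bam_molecule`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_molecule <- function(x) {
  stopifnot(is_molecule(x))
  key <- x$inchikey
  if (nchar(key) != 27L || substr(key, 15, 15) != "-" ||
      substr(key, 26, 26) != "-") {
    stopf("malformed InChIKey: %s", key)
  }
  if (!is.numeric(x$monoisotopic_mass) || x$monoisotopic_mass <= 0) {
    stopf("non-positive monoisotopic mass")
  }
  if (length(x$atom_codes) != x$n_heavy) {
    stopf("atom code vector does not cover the heavy atoms")
  }
  invisible(x)
}
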