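# Spectrum container and MGF / MSP readers.

ADDUCT_SHIFTS <- c(
  "[M+H]+"   = 1.007276466,
  "[M+Na]+"  = 22.98922,
  "[M+NH4]+" = 18.033823,
  "[M-H]-"   = -1.007276466
)

#' Construct an MS/MS spectrum
#'
#' Peaks are sorted by ascending m/z; peaks sharing an m/z value are merged
#' (maximum intensity) so the m/z axis is strictly ascending.
#'
#' @param id Spectrum identifier (unique within a data set).
#' @param precursor_mz Precursor m/z (Th), positive.
#' @param peaks Two-column matrix or data.frame `(mz, intensity)`; at least
#'   one peak, non-negative intensities.
#' @param precursor_charge Integer charge state (>= 1).
#' @param adduct Adduct label; `"[M+H]+"` by default.
#' @param annotation Optional `bam_molecule` structure annotation.
#' @return A `bam_spectrum`.
#' @export
spectrum <- function(id, precursor_mz, peaks, precursor_charge = 1L,
                     adduct = "[M+H]+", annotation = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  precursor_mz <- as.numeric(precursor_mz)
  if (!isTRUE(precursor_mz > 0)) stopf("precursor_mz must be > 0 (spectrum %s)", id)
  precursor_charge <- as.integer(precursor_charge)
  if (!isTRUE(precursor_charge >= 1L)) {
    stopf("precursor_charge must be >= 1 (spectrum %s)", id)
  }
  peaks <- as.matrix(peaks)
  if (nrow(peaks) < 1L || ncol(peaks) != 2L) {
    stopf("peaks must be a non-empty two-column (mz, intensity) table (spectrum %s)", id)
  }
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (any(peaks[, "intensity"] < 0)) stopf("negative intensity (spectrum %s)", id)
  if (any(!is.finite(peaks))) stopf("non-finite peak values (spectrum %s)", id)
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  if (anyDuplicated(peaks[, "mz"])) {
    agg <- tapply(peaks[, "intensity"], peaks[, "mz"], max)
    peaks <- cbind(mz = as.numeric(names(agg)), intensity = as.numeric(agg))
  }
  if (!is.null(annotation)) stopifnot(is_molecule(annotation))
  structure(
    list(id = id, precursor_mz = precursor_mz,
         precursor_charge = precursor_charge, adduct = adduct,
         peaks = peaks, annotation = annotation),
    class = "bam_spectrum"
  )
}

is_spectrum <- function(x) inherits(x, "bam_spectrum")

#' @export
print.bam_spectrum <- function(x, ...) {
  cat(sprintf("<bam_spectrum> %s  precursor %.4f (%d%s, %s)  %d peaks%s\n",
              x$id, x$precursor_mz, x$precursor_charge,
              if (grepl("-", x$adduct, fixed = TRUE)) "-" else "+",
              x$adduct, nrow(x$peaks),
              if (is.null(x$annotation)) "" else paste0("  [", x$annotation$smiles, "]")))
  invisible(x)
}

#' Neutral monoisotopic mass implied by a spectrum's precursor
#'
#' `neutral = charge * precursor_mz - charge * adduct_shift`, with the adduct
#' shift per charge taken from a small built-in table (default `[M+H]+`,
#' proton 1.00728 Da).  Unknown adducts fall back to protonation.
#'
#' @param s A `bam_spectrum`.
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(s) {
  stopifnot(is_spectrum(s))
  shift <- if (s$adduct %in% names(ADDUCT_SHIFTS)) {
    ADDUCT_SHIFTS[[s$adduct]]
  } else {
    ADDUCT_SHIFTS[["[M+H]+"]]
  }
  s$precursor_charge * s$precursor_mz - s$precursor_charge * shift
}

#' Read spectra from MGF or MSP files
#'
#' MGF records are `BEGIN IONS`/`END IONS` blocks with `KEY=value` headers;
#' MSP records are blank-line separated blocks with `Key: value` headers and a
#' `Num Peaks:` count.  A structure annotation is populated when a `SMILES`
#' (or `INCHI`-free SMILES-bearing) field is present.  Records without a
#' precursor m/z are skipped with a warning; malformed records raise an error
#' naming the record index.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mgf"` or `"msp"`.
#' @return List of `bam_spectrum`, peaks sorted.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "msp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("spectra file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "msp") "msp" else "mgf"
  }
  raw <- switch(format, mgf = parse_mgf(path), msp = parse_msp(path))
  # one bridge call for all annotations
  ann_smiles <- unique(unlist(lapply(raw, `[[`, "smiles")))
  ann <- if (length(ann_smiles)) molecules(ann_smiles, on_error = "skip") else list()
  out <- list()
  for (rec in raw) {
    a <- if (!is.null(rec$smiles)) ann[[rec$smiles]] else NULL
    out[[length(out) + 1L]] <- spectrum(
      id = rec$id, precursor_mz = rec$precursor_mz, peaks = rec$peaks,
      precursor_charge = rec$charge, adduct = rec$adduct, annotation = a)
  }
  out
}

parse_peak_lines <- function(lines, idx) {
  toks <- unlist(strsplit(trimws(lines), "[;[:space:]]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (any(is.na(vals)) || length(vals) %% 2L != 0L || length(vals) == 0L) {
    stopf("malformed peak list in record %d", idx)
  }
  matrix(vals, ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("mz", "intensity")))
}

parse_charge <- function(x) {
  if (is.null(x)) return(1L)
  n <- suppressWarnings(as.integer(gsub("[+-]", "", x)))
  if (is.na(n) || n < 1L) 1L else n
}

parse_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^\\s*BEGIN IONS\\s*$", lines, ignore.case = TRUE)
  ends <- grep("^\\s*END IONS\\s*$", lines, ignore.case = TRUE)
  if (length(begins) != length(ends) || any(ends < begins)) {
    stopf("unbalanced BEGIN IONS/END IONS in %s", path)
  }
  out <- list()
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_kv <- grepl("^[A-Za-z][A-Za-z0-9_]*=", block)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    hdr <- stats::setNames(as.list(trimws(vals)), keys)
    if (is.null(hdr$PEPMASS)) {
      warning(sprintf("MGF record %d skipped: no PEPMASS", k))
      next
    }
    pmz <- suppressWarnings(as.numeric(strsplit(trimws(hdr$PEPMASS), "\\s+")[[1]][1]))
    if (is.na(pmz)) stopf("malformed PEPMASS in record %d", k)
    peak_lines <- block[!is_kv]
    if (length(peak_lines) == 0L) stopf("record %d has no peaks", k)
    out[[length(out) + 1L]] <- list(
      id = hdr$TITLE %||% sprintf("spectrum_%d", k),
      precursor_mz = pmz,
      charge = parse_charge(hdr$CHARGE),
      adduct = hdr$ADDUCT %||% "[M+H]+",
      smiles = hdr$SMILES,
      peaks = parse_peak_lines(peak_lines, k))
  }
  out
}

parse_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  out <- list()
  k <- 0L
  for (g in unique(grp[!blank])) {
    block <- lines[!blank & grp == g]
    if (!length(block)) next
    k <- k + 1L
    is_kv <- grepl("^[A-Za-z][A-Za-z0-9_ ]*:", block)
    kv <- block[is_kv]
    keys <- toupper(gsub("\\s", "", sub(":.*$", "", kv)))
    vals <- trimws(sub("^[^:]*:", "", kv))
    hdr <- stats::setNames(as.list(vals), keys)
    pmz_raw <- hdr$PRECURSORMZ %||% hdr$PEPMASS
    if (is.null(pmz_raw)) {
      warning(sprintf("MSP record %d skipped: no PrecursorMZ", k))
      next
    }
    pmz <- suppressWarnings(as.numeric(pmz_raw))
    if (is.na(pmz)) stopf("malformed PrecursorMZ in record %d", k)
    peak_lines <- block[!is_kv]
    peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
    if (!length(peak_lines)) stopf("record %d has no peaks", k)
    out[[length(out) + 1L]] <- list(
      id = hdr$NAME %||% sprintf("spectrum_%d", k),
      precursor_mz = pmz,
      charge = parse_charge(hdr$CHARGE),
      adduct = hdr$PRECURSORTYPE %||% "[M+H]+",
      smiles = hdr$SMILES,
      peaks = parse_peak_lines(peak_lines, k))
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra List of `bam_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(is_spectrum(s))
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", s$id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", s$precursor_charge), con)
    writeLines(sprintf("ADDUCT=%s", s$adduct), con)
    if (!is.null(s$annotation)) {
      writeLines(sprintf("SMILES=%s", s$annotation$smiles), con)
    }
    writeLines(sprintf("%.6f %.6f", s$peaks[, "mz"], s$peaks[, "intensity"]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
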