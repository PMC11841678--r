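# JSON-over-files bridge to the bundled RDKit helper script.
#
# Every chemistry primitive (canonical SMILES, InChIKey, monoisotopic mass,
# Morgan fingerprints, MCS rule extraction, molecular editing) runs through
# inst/python/chem_bridge.py.  Calls are batched: one process launch serves a
# whole vector of molecules, so pipeline stages issue a handful of bridge
# calls rather than one per molecule.

.bam <- new.env(parent = emptyenv())

bridge_script <- function() {
  system.file("python", "chem_bridge.py", package = "bamanno", mustWork = TRUE)
}

bam_python <- function() {
  if (!is.null(.bam$python)) return(.bam$python)
  p <- Sys.getenv("BAMANNO_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) {
    stopf("no python interpreter found; set BAMANNO_PYTHON",
          class = "bam_bridge_error")
  }
  .bam$python <- p
  p
}

bridge_call <- function(op, payload = list()) {
  req <- tempfile("bam_req_", fileext = ".json")
  resp <- tempfile("bam_resp_", fileext = ".json")
  on.exit(unlink(c(req, resp)), add = TRUE)
  jsonlite::write_json(c(list(op = op), payload), req,
                       auto_unbox = TRUE, digits = NA, null = "null")
  status <- suppressWarnings(
    system2(bam_python(), c(shQuote(bridge_script()), shQuote(req), shQuote(resp)),
            stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(resp)) {
    stopf("chemistry bridge failed (op '%s', exit status %s)", op,
          paste(status, collapse = ","), class = "bam_bridge_error")
  }
  out <- jsonlite::read_json(resp, simplifyVector = FALSE)
  if (!isTRUE(out$ok)) {
    stopf("chemistry bridge error in op '%s': %s", op,
          out$error %||% "unknown", class = "bam_bridge_error")
  }
  out$result
}
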