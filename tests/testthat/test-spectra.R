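# Spectrum construction and MGF / MSP parsing.

test_that("spectrum constructor enforces invariants and sorts peaks", {
  s <- spectrum("s1", 200.1, cbind(c(150, 80, 80), c(1, 2, 5)))
  expect_true(all(diff(s$peaks[, "mz"]) > 0))
  expect_equal(unname(s$peaks[1, "intensity"]), 5)  # duplicate mz merged by max
  expect_error(spectrum("s2", -1, cbind(100, 1)))
  expect_error(spectrum("s3", 100, cbind(100, -1)))
  expect_error(spectrum("s4", 100, matrix(numeric(0), ncol = 2)))
  expect_error(spectrum("s5", 100, cbind(100, 1), precursor_charge = 0))
})

test_that("MGF round-trips, sorts unsorted peaks, skips records without PEPMASS", {
  path <- withr_local_tempfile()
  writeLines(c(
    "BEGIN IONS", "TITLE=one", "PEPMASS=301.1 1234.0", "CHARGE=1+",
    "SMILES=CCO",
    "200.2 5.0", "100.1 10.0",           # unsorted on purpose
    "END IONS",
    "BEGIN IONS", "TITLE=no_precursor", "100.0 1.0", "END IONS",
    "BEGIN IONS", "TITLE=two", "PEPMASS=402.2", "CHARGE=2+",
    "150.0 1.0", "END IONS"), path)
  expect_warning(sp <- read_spectra(path, format = "mgf"), "no PEPMASS")
  expect_length(sp, 2L)
  expect_identical(sp[[1]]$id, "one")
  expect_equal(sp[[1]]$precursor_mz, 301.1)
  expect_identical(sp[[1]]$annotation$smiles, "CCO")
  expect_equal(sp[[1]]$peaks[, "mz"], c(100.1, 200.2))
  expect_identical(sp[[2]]$precursor_charge, 2L)

  # write + re-read preserves content
  out <- withr_local_tempfile()
  write_mgf(sp, out)
  sp2 <- read_spectra(out, format = "mgf")
  expect_equal(sp2[[1]]$peaks, sp[[1]]$peaks, tolerance = 1e-6)
  expect_identical(sp2[[1]]$annotation$inchikey, sp[[1]]$annotation$inchikey)
})

test_that("malformed MGF records raise errors naming the record", {
  path <- withr_local_tempfile()
  writeLines(c("BEGIN IONS", "TITLE=bad", "PEPMASS=100", "END IONS"), path)
  expect_error(read_spectra(path, format = "mgf"), "record 1")
  writeLines(c("BEGIN IONS", "TITLE=bad", "PEPMASS=100",
               "100 not_a_number", "END IONS"), path)
  expect_error(read_spectra(path, format = "mgf"), "record 1")
})

test_that("MSP records parse with Num Peaks and PrecursorMZ headers", {
  path <- withr_local_tempfile()
  writeLines(c(
    "Name: alpha", "PrecursorMZ: 180.5", "Num Peaks: 2",
    "80.0 1.0; 90.0 2.0",
    "",
    "Name: beta", "PrecursorMZ: 220.0", "SMILES: CCO", "Num Peaks: 1",
    "120.0\t3.0"), path)
  sp <- read_spectra(path, format = "msp")
  expect_length(sp, 2L)
  expect_identical(sp[[1]]$id, "alpha")
  expect_equal(nrow(sp[[1]]$peaks), 2L)
  expect_identical(sp[[2]]$annotation$smiles, "CCO")
})

test_that("neutral mass honors adduct and charge", {
  s <- spectrum("x", 101.00728, cbind(50, 1))
  expect_equal(neutral_mass(s), 100.0, tolerance = 1e-4)
  s2 <- spectrum("y", 51.0073, cbind(50, 1), precursor_charge = 2L)
  expect_equal(neutral_mass(s2), 2 * 51.0073 - 2 * 1.007276466, tolerance = 1e-6)
  s3 <- spectrum("z", 123.0, cbind(50, 1), adduct = "[M+Na]+")
  expect_equal(neutral_mass(s3), 123 - 22.98922, tolerance = 1e-4)
})
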