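test_that("CSV reading reorders descending grids and validates input", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,value",
               "2504.0,0.5", "2503.0,0.4", "2502.0,0.3", "2501.0,0.2",
               "2500.0,0.1"), f)
  s <- readSpectrum(f)
  expect_equal(wavenumbers(s), c(2500, 2501, 2502, 2503, 2504))
  expect_equal(intensities(s), c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_identical(spectrumRole(s), "absorbance")

  writeLines(c("wavenumber_cm-1,value", "2500.0,0.1", "2500.0,0.2",
               "2501.0,0.3"), f)
  expect_error(readSpectrum(f), "duplicated")

  writeLines(c("bad_header,value", "2500.0,0.1"), f)
  expect_error(readSpectrum(f), "line 1")

  writeLines(c("wavenumber_cm-1,value", "2500.0,0.1", "2501.0,oops"), f)
  expect_error(readSpectrum(f), "line 3")
})

test_that("CSV and JCAMP-DX round trips preserve data to 1e-9", {
  g <- analysisGrid()
  s <- Spectrum(g, pseudoVoigt(g, 2480, 140, 0.73, 0.2),
                role = "molar_absorptivity")
  fc <- tempfile(fileext = ".csv")
  writeSpectrum(s, fc)
  s2 <- readSpectrum(fc)
  expect_lt(max(abs(wavenumbers(s2) - g)), 1e-9)
  expect_lt(max(abs(intensities(s2) - intensities(s))), 1e-9)
  expect_identical(spectrumRole(s2), "molar_absorptivity")

  fj <- tempfile(fileext = ".jdx")
  writeSpectrum(s, fj, format = "jcamp")
  s3 <- readSpectrum(fj)
  expect_identical(spectrumRole(s3), "molar_absorptivity")
  expect_lt(max(abs(wavenumbers(s3) - g)), 1e-9)
  expect_lt(max(abs(intensities(s3) - intensities(s))), 1e-9)

  ## unsupported JCAMP forms are rejected, not misread
  txt <- readLines(fj)
  txt <- sub("XYDATA=\\(X\\+\\+\\(Y..Y\\)\\)", "XYDATA=(XY..XY)", txt)
  writeLines(txt, fj)
  expect_error(readSpectrum(fj), "only \\(X\\+\\+\\(Y..Y\\)\\)")
})

test_that("Beer-Lambert conversion matches hand arithmetic and is linear", {
  g <- seq(2400, 2600, by = 10)
  s <- Spectrum(g, rep(0.5, length(g)))
  e <- toMolarAbsorptivity(s, pathLength = 28.4, cHDO = 0.5)
  expect_equal(unique(round(intensities(e), 1)), 352.1)
  expect_identical(spectrumRole(e), "molar_absorptivity")

  z <- toMolarAbsorptivity(Spectrum(g, rep(0, length(g))), 28.4, 0.5)
  expect_true(all(intensities(z) == 0))

  expect_error(toMolarAbsorptivity(s, 0, 0.5), "path length")
  expect_error(toMolarAbsorptivity(s, 28.4, -1), "molarity")

  ## linear in A, inverse-linear in c*d
  set.seed(1)
  a <- runif(length(g))
  s1 <- Spectrum(g, a)
  e1 <- toMolarAbsorptivity(s1, 30, 0.4)
  e2 <- toMolarAbsorptivity(Spectrum(g, 3 * a), 30, 0.4)
  e3 <- toMolarAbsorptivity(s1, 60, 0.8)
  expect_equal(intensities(e2), 3 * intensities(e1))
  expect_equal(intensities(e3), intensities(e1) / 4)
})

test_that("resampling is exact on linear data and conserves band area", {
  g <- seq(2300, 2700, by = 2)
  ramp <- Spectrum(g, 0.1 + 0.002 * (g - 2300))
  mid <- resampleSpectrum(ramp, g[-length(g)] + 1)
  expect_lt(max(abs(intensities(mid) -
                      (intensities(ramp)[-1] +
                         intensities(ramp)[-length(g)]) / 2)), 1e-9)

  same <- resampleSpectrum(ramp, g)
  expect_equal(intensities(same), intensities(ramp))

  band <- Spectrum(g, pseudoVoigt(g, 2500, 120, 1, 0))
  dense <- resampleSpectrum(band, seq(2300, 2700, by = 1))
  a1 <- pracma::trapz(wavenumbers(band), intensities(band))
  a2 <- pracma::trapz(wavenumbers(dense), intensities(dense))
  expect_lt(abs(a2 - a1) / a1, 1e-4)

  expect_error(resampleSpectrum(band, seq(2200, 2700, 1)), "beyond")
})

test_that("scaleToMax normalises to unit peak and is idempotent", {
  g <- seq(2400, 2600, by = 5)
  s <- Spectrum(g, pseudoVoigt(g, 2500, 80, 2, 0))
  u <- scaleToMax(s)
  expect_equal(max(intensities(u)), 1)
  expect_equal(intensities(scaleToMax(u)), intensities(u))
  expect_error(scaleToMax(Spectrum(g, rep(-1, length(g)))), "non-positive")
})

test_that("Spectrum validity enforces the class invariants", {
  expect_error(Spectrum(c(2500, 2502, 2501, 2503), 1:4), "ascending")
  expect_error(Spectrum(c(2500, 2501, 2501, 2502), 1:4), "duplicated")
  expect_error(methods::new("Spectrum", grid = c(2500, 2501),
                            values = c(1, 2), role = "banana"),
               "role")
  expect_error(methods::new("Spectrum", grid = c(2500, 2501),
                            values = c(1, NaN), role = "absorbance"),
               "finite")
})

test_that("manifests round-trip through YAML and series load correctly", {
  td <- tempfile()
  tr <- peptideTruth()
  ser <- makeBinarySeries(tr, seed = 5, dir = td)
  man <- readManifest(ser$manifest)
  expect_s4_class(man, "SeriesManifest")
  expect_equal(man@entries$molality, ser$molalities)
  expect_equal(unname(man@composition), 1)

  loaded <- loadSeries(man)
  ## Beer-Lambert inversion on write, conversion on read: exact round trip
  expect_lt(max(abs(intensities(loaded$bulk) - intensities(ser$bulk))),
            1e-8)
  expect_lt(max(abs(intensities(loaded$spectra[[3]]) -
                      intensities(ser$spectra[[3]]))), 1e-8)

  ## fewer than 3 non-zero molalities violates the manifest invariant
  expect_error(seriesManifest(c("a.csv", "b.csv"), c(0.5, 1), c(s = 1),
                              "bulk.csv", 0.5),
               "3 distinct")
  expect_error(seriesManifest(c("a.csv", "b.csv", "c.csv"), c(0.5, 1, 1.5),
                              c(s = 0.7, t = 0.7), "bulk.csv", 0.5),
               "sum to 1")
})
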