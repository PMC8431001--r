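test_that("theoretical spectrum is the N-weighted mixture of components", {
  g <- analysisGrid()
  epsP <- Spectrum(g, pseudoVoigt(g, 2450, 100, 1) /
                     pracma::trapz(g, pseudoVoigt(g, 2450, 100, 1)),
                   role = "affected")
  epsO <- Spectrum(g, pseudoVoigt(g, 2550, 100, 1) /
                     pracma::trapz(g, pseudoVoigt(g, 2550, 100, 1)),
                   role = "affected")
  ## boundaries
  t0 <- theoreticalAffected(epsP, 5, epsO, 3, 0)
  expect_equal(intensities(t0$spectrum), intensities(epsP))
  expect_equal(t0$N, 5)
  t1 <- theoreticalAffected(epsP, 5, epsO, 3, 1)
  expect_equal(intensities(t1$spectrum), intensities(epsO))
  expect_equal(t1$N, 3)
  ## x = 0.5 with equal N: pointwise mean (direct weighted-sum oracle)
  th <- theoreticalAffected(epsP, 5, epsO, 5, 0.5)
  expect_equal(th$N, 5)
  expect_lt(max(abs(intensities(th$spectrum) -
                      (intensities(epsP) + intensities(epsO)) / 2)), 1e-12)
  expect_error(theoreticalAffected(epsP, 5, epsO, 3, 1.2), "0, 1")
})

test_that("delta-N classification follows the sign convention", {
  expect_identical(classifyDeltaN(4, 6)$label, "shared")
  expect_equal(classifyDeltaN(4, 6)$deltaN, -2)
  expect_identical(classifyDeltaN(9, 6)$label, "excess")
  expect_identical(classifyDeltaN(6, 6)$label, "none")
  expect_identical(classifyDeltaN(6.05, 6, epsTol = 0.1)$label, "none")
  expect_error(classifyDeltaN(-1, 6), "must be > 0")
})

test_that("non-interacting construction decomposes to w = 1, zero share", {
  tp <- peptideTruth()
  to <- osmolyteTruth()
  for (x in c(0.2, 0.5, 0.8)) {
    tern <- makeTernarySeries(tp, to, x, seed = 11)
    r <- extractAffectedWater(tern$spectra, tern$molalities, tern$bulk)
    dec <- decomposeSharedExcess(tern$epsP, tp$N, tern$epsO, to$N, x,
                                 affectedSpectrum(r), r@N)
    expect_lt(abs(dec@wP - 1), 1e-3)
    expect_lt(abs(dec@wO - 1), 1e-3)
    expect_lt(sharePercent(dec), 0.01)
    expect_identical(interactionLabel(dec), "none")
  }
})

test_that("a distinct shared band with w_o = 0 is recovered (noiseless)", {
  tp <- peptideTruth()
  to <- osmolyteTruth()
  shc <- list(bandSpec(2416, 120, 30, 0.1))
  Nsh <- sharedCountForShare(10, tp, to, shc, x = 0.5, wP = 1, wO = 0)
  tern <- makeTernarySeries(tp, to, 0.5,
                            shared = list(components = shc, N = Nsh),
                            wP = 1, wO = 0, seed = 3)
  r <- extractAffectedWater(tern$spectra, tern$molalities, tern$bulk)
  dec <- decomposeSharedExcess(tern$epsP, tp$N, tern$epsO, to$N, 0.5,
                               affectedSpectrum(r), r@N)
  expect_lt(abs(sharePercent(dec) - 10), 0.05)
  expect_lt(dec@wO, 1e-3)
  expect_lt(abs(dec@wP - 1), 1e-3)
  ## recovered shared spectrum matches the generator band
  truthSh <- intensities(tern$epsShared)
  got <- intensities(sharedSpectrum(dec))
  expect_lt(sqrt(mean((got - truthSh)^2)) / max(truthSh), 0.01)
})

test_that("bookkeeping invariants hold exactly", {
  tp <- peptideTruth()
  to <- osmolyteTruth()
  shc <- list(bandSpec(2430, 140, 20, 0.2))
  tern <- makeTernarySeries(tp, to, 0.4,
                            shared = list(components = shc, N = 1.2),
                            wP = 0.8, wO = 0.9, seed = 5)
  r <- extractAffectedWater(tern$spectra, tern$molalities, tern$bulk)
  dec <- decomposeSharedExcess(tern$epsP, tp$N, tern$epsO, to$N, 0.4,
                               affectedSpectrum(r), r@N)
  ## water bookkeeping: w_p (1-x) N_p + w_o x N_o + N_sh = N_exp
  expect_equal(dec@wP * 0.6 * tp$N + dec@wO * 0.4 * to$N + sharedCount(dec),
               r@N, tolerance = 1e-12)
  ## intensity bookkeeping: components sum back to N_exp eps_exp
  total <- dec@wP * 0.6 * tp$N * intensities(tern$epsP) +
    dec@wO * 0.4 * to$N * intensities(tern$epsO) +
    sharedCount(dec) * intensities(sharedSpectrum(dec))
  expect_lt(max(abs(total - r@N * intensities(affectedSpectrum(r)))), 1e-6)
})

test_that("solver objective matches an exhaustive 0.01 grid on random
           instances", {
  for (seed in 1:10) {
    inst <- randomLPInstance(seed)
    g <- inst$grid
    delta <- rep(0.01, length(g))
    oracle <- hydroshell:::.decomposeGridOracle(
      (1 - inst$x) * inst$NP * inst$epsP, inst$x * inst$NO * inst$epsO,
      inst$C, (1 - inst$x) * inst$NP, inst$x * inst$NO, delta)
    dec <- decomposeSharedExcess(
      Spectrum(g, inst$epsP, role = "affected"), inst$NP,
      Spectrum(g, inst$epsO, role = "affected"), inst$NO, inst$x,
      Spectrum(g, inst$C / inst$NExp, role = "affected"), inst$NExp,
      delta = 0.01, supportFloor = 0)
    solverObj <- dec@wP * inst$a + dec@wO * inst$b
    ## no feasible grid pair beats the solver
    expect_gte(solverObj, oracle["obj"] - 1e-9)
    ## and the solver's solution is itself feasible
    r <- inst$C - dec@wP * inst$a * inst$epsP - dec@wO * inst$b * inst$epsO
    expect_gte(min(r), -0.01 - 1e-9)
  }
})

test_that("infeasible experimental spectra raise a validation error", {
  g <- analysisGrid()
  epsP <- Spectrum(g, pseudoVoigt(g, 2450, 100, 1), role = "affected")
  epsO <- Spectrum(g, pseudoVoigt(g, 2550, 100, 1), role = "affected")
  bad <- Spectrum(g, pseudoVoigt(g, 2500, 100, 1) - 0.5, role = "affected")
  expect_error(decomposeSharedExcess(epsP, 5, epsO, 3, 0.5, bad, 4),
               "negative dips")
})
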