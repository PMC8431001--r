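test_that("band parameters of a Gaussian match the closed form", {
  g <- analysisGrid()
  s <- Spectrum(g, pseudoVoigt(g, 2500, 160, 1, 0),
                role = "molar_absorptivity")
  bp <- bandParameters(s)
  expect_lt(abs(bp$nu_max - 2500), 0.01)
  expect_lt(abs(bp$nu_grav - 2500), 0.01)
  expect_lt(abs(bp$fwhh - 160), 0.05)
  closed <- (160 / (2 * sqrt(2 * log(2)))) * sqrt(2 * pi)
  expect_lt(abs(bp$intensity - closed) / closed, 0.001)
})

test_that("composite-band parameters match a dense quadrature oracle", {
  g <- analysisGrid()
  f <- function(nu) pseudoVoigt(nu, 2450, 40 * 2.3548, 1, 0) +
    pseudoVoigt(nu, 2550, 80 * 2.3548, 0.5, 0)
  s <- Spectrum(g, f(g), role = "molar_absorptivity")
  bp <- bandParameters(s)
  gg <- seq(2200, 2800, by = 0.01)   # dense oracle grid
  y <- f(gg)
  nuMaxO <- gg[which.max(y)]
  nuGravO <- pracma::trapz(gg, gg * y) / pracma::trapz(gg, y)
  half <- max(y) / 2
  lo <- gg[min(which(y >= half))]
  hi <- gg[max(which(y >= half))]
  intO <- pracma::trapz(gg, y)
  expect_lt(abs(bp$nu_max - nuMaxO), 0.1)
  expect_lt(abs(bp$nu_grav - nuGravO), 0.1)
  expect_lt(abs(bp$fwhh - (hi - lo)) / (hi - lo), 0.001)
  expect_lt(abs(bp$intensity - intO) / intO, 0.001)
})

test_that("band parameters are scale-invariant except intensity", {
  g <- analysisGrid()
  s1 <- Spectrum(g, pseudoVoigt(g, 2480, 150, 1, 0.2),
                 role = "molar_absorptivity")
  s2 <- Spectrum(g, 7.3 * intensities(s1), role = "molar_absorptivity")
  b1 <- bandParameters(s1)
  b2 <- bandParameters(s2)
  expect_equal(b2$nu_max, b1$nu_max)
  expect_equal(b2$nu_grav, b1$nu_grav)
  expect_equal(b2$fwhh, b1$fwhh)
  expect_equal(b2$intensity, 7.3 * b1$intensity)
})

test_that("well separated sub-bands trigger the ambiguity warning", {
  g <- analysisGrid()
  y <- pseudoVoigt(g, 2350, 60, 1, 0) + pseudoVoigt(g, 2650, 60, 0.9, 0)
  expect_warning(bandParameters(Spectrum(g, y)), "ambiguous")
  expect_error(bandParameters(Spectrum(g, -y)), "positive peak")
})

test_that("affine frequency-distance maps give the closed-form transform", {
  g <- analysisGrid()
  knots <- data.frame(R_angstrom = seq(2.0, 4.0, by = 0.25))
  knots$nu_cm1 <- 1000 + 600 * knots$R_angstrom
  map <- frequencyDistanceMap(knots)

  ## flat band -> uniform P with unit area
  flat <- Spectrum(g, rep(1, length(g)), role = "affected")
  pu <- toDistanceDistribution(flat, map)
  expect_lt(diff(range(distanceDensity(pu))) / max(distanceDensity(pu)),
            1e-9)
  expect_equal(pracma::trapz(distanceGrid(pu), distanceDensity(pu)), 1,
               tolerance = 1e-9)

  ## Gaussian band -> Gaussian in R with mapped mean and width
  s <- Spectrum(g, pseudoVoigt(g, 2500, 120, 1, 0), role = "affected")
  p <- toDistanceDistribution(s, map)
  expect_equal(pracma::trapz(distanceGrid(p), distanceDensity(p)), 1,
               tolerance = 1e-6)
  expect_lt(abs(distanceMode(p) - (2500 - 1000) / 600), 1e-6)
  expect_lt(abs(distanceMean(p) - (2500 - 1000) / 600), 1e-6)
  sg <- 120 / (2 * sqrt(2 * log(2))) / 600
  expect_lt(abs(max(distanceDensity(p)) - 1 / (sg * sqrt(2 * pi))), 1e-6)

  ## non-monotone knots rejected
  bad <- knots
  bad$nu_cm1[3] <- bad$nu_cm1[5]
  expect_error(frequencyDistanceMap(bad), "monotone")
})

test_that("delta-P differences vanish for identical inputs and integrate
           to zero", {
  g <- analysisGrid()
  knots <- data.frame(R_angstrom = seq(2.0, 4.0, by = 0.25))
  knots$nu_cm1 <- 1000 + 600 * knots$R_angstrom
  map <- frequencyDistanceMap(knots)
  p1 <- toDistanceDistribution(Spectrum(g, pseudoVoigt(g, 2480, 110, 1)),
                               map)
  p2 <- toDistanceDistribution(Spectrum(g, pseudoVoigt(g, 2520, 140, 0.8)),
                               map)
  d0 <- deltaP(p1, p1)
  expect_lt(max(abs(d0$delta)), 1e-12)
  d <- deltaP(p1, p2)
  expect_lt(abs(pracma::trapz(d$r, d$delta)), 1e-6)

  ## closed form at one point for two Gaussians in R (means 2.80/2.82,
  ## sigma 0.05): build them through the affine map
  nu1 <- 1000 + 600 * 2.80
  nu2 <- 1000 + 600 * 2.82
  fw <- 0.05 * 2 * sqrt(2 * log(2)) * 600
  q1 <- toDistanceDistribution(Spectrum(g, pseudoVoigt(g, nu1, fw, 1)), map,
                               rStep = 1e-4)
  q2 <- toDistanceDistribution(Spectrum(g, pseudoVoigt(g, nu2, fw, 1)), map,
                               rStep = 1e-4)
  dd <- deltaP(q1, q2)
  at <- which.min(abs(dd$r - 2.80))
  ## the distributions are normalised on the transform's distance range, so
  ## the closed form is the truncated-normal density difference
  lo <- min(distanceGrid(q1)); hi <- max(distanceGrid(q1))
  tn <- function(x, m) stats::dnorm(x, m, 0.05) /
    (stats::pnorm(hi, m, 0.05) - stats::pnorm(lo, m, 0.05))
  expect_lt(abs(dd$delta[at] - (tn(2.80, 2.80) - tn(2.80, 2.82))), 1e-5)
})

test_that("a nonlinear map can invert the ordering of band maxima", {
  g <- analysisGrid()
  map <- defaultFrequencyDistanceMap()
  ## band A peaks at higher wavenumber but carries a heavy red shoulder;
  ## band B is symmetric at a slightly lower wavenumber
  yA <- pseudoVoigt(g, 2492, 80, 1, 0) + pseudoVoigt(g, 2360, 110, 0.95, 0)
  yB <- pseudoVoigt(g, 2486, 150, 1, 0)
  bA <- suppressWarnings(bandParameters(Spectrum(g, yA)))
  bB <- bandParameters(Spectrum(g, yB))
  pA <- toDistanceDistribution(Spectrum(g, yA, role = "affected"), map)
  pB <- toDistanceDistribution(Spectrum(g, yB, role = "affected"), map)
  ## band maxima: A above B; distance modes: A below B (order inverted)
  expect_gt(bA$nu_max, bB$nu_max)
  expect_lt(distanceMode(pA), distanceMode(pB))
})

test_that("negative noise is clipped and flagged in the transform", {
  g <- analysisGrid()
  y <- pseudoVoigt(g, 2500, 120, 1)
  y[10:20] <- -1e-7
  p <- toDistanceDistribution(Spectrum(g, y, role = "affected"),
                              defaultFrequencyDistanceMap(), delta = 1e-6)
  expect_gt(p@meta$clippedFraction, 0)
  expect_true(all(distanceDensity(p) >= 0))
})
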