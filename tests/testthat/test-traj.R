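test_that("geometric centres honour periodic boundaries", {
  box <- c(10, 10, 10)
  co <- rbind(c(2, 3, 4))
  expect_equal(geometricCenter(co, box, 1), c(2, 3, 4))
  co2 <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(geometricCenter(co2, box, 1:2), c(1, 0, 0))
  ## pair straddling the boundary: centre at x = 0 (mod box)
  co3 <- rbind(c(9.5, 5, 5), c(0.5, 5, 5))
  expect_equal(geometricCenter(co3, box, 1:2), c(0, 5, 5))
  ## matches the brute-force image-enumeration oracle on random fragments
  set.seed(21)
  for (rep in 1:20) {
    co <- matrix(runif(12, 0, 10), ncol = 3)
    co[2:4, ] <- matrix(rep(co[1, ], each = 3), ncol = 3) +
      matrix(runif(9, -2, 2), ncol = 3)   # compact fragment
    co <- co - 10 * floor(co / 10)
    expect_equal(geometricCenter(co, box, 1:4),
                 bruteForceCenter(co, box, 1:4), tolerance = 1e-9)
  }
  ## a chain spanning more than half the box is ambiguous
  wide <- rbind(c(0, 5, 5), c(4, 5, 5), c(8, 5, 5))
  expect_error(geometricCenter(wide, box, 1:3), "ambiguous")
  expect_error(geometricCenter(wide, box, integer(0)), "empty")
  expect_error(geometricCenter(wide, box, c(1, 9)), "out of range")
})

test_that("RDF: uniform gas gives g = 1, single atom the closed-form bin", {
  ig <- makeTrajectory("ideal_gas", box = 20, nFrames = 100, nAtoms = 800,
                       seed = 31)
  rdf <- rdfAroundCenter(ig$trajectory, fragment = 1, selection = 2:800,
                         rMax = 5, binWidth = 0.25)
  far <- rdf[rdf$r > 1, ]
  expect_true(all(abs(far$g - 1) <= 3 * far$gSE))
  ## pair-count conservation
  fs <- makeTrajectory("fixed_radius_shell", box = 20, nFrames = 6, k = 1,
                       d = 3.0, seed = 32)
  r2 <- rdfAroundCenter(fs$trajectory, fragment = 1, selection = 2,
                        rMax = 5, binWidth = 0.08)
  expect_equal(sum(r2$count), 6)
  hit <- r2[r2$count > 0, ]
  expect_equal(nrow(hit), 1L)
  vShell <- (4 * pi / 3) * ((hit$r + 0.04)^3 - (hit$r - 0.04)^3)
  expect_equal(hit$g, 8000 / vShell, tolerance = 1e-9)
  expect_error(rdfAroundCenter(fs$trajectory, 1, 2, rMax = 11),
               "half the smallest box")
  expect_error(rdfAroundCenter(fs$trajectory, 1, integer(0)), "empty")
})

test_that("orientation histograms: aligned is degenerate, isotropic follows
           sin(theta)", {
  al <- makeTrajectory("oriented_osmolytes", box = 30, nFrames = 2,
                       nProbes = 200, law = "aligned", seed = 33)
  aa <- angleDistribution(al$trajectory, 1, al$truth$probes, c(0, 13),
                          angleBin = 5)
  expect_equal(aa$density[[1]][1] * 5, 1)

  iso <- makeTrajectory("oriented_osmolytes", box = 30, nFrames = 25,
                        nProbes = 2000, law = "isotropic", seed = 34)
  ai <- angleDistribution(iso$trajectory, 1, iso$truth$probes, c(0, 6, 13),
                          angleBin = 5, keepAngles = TRUE)
  ## each distance bin is a unit-area density
  for (j in 1:2) expect_equal(sum(ai$density[[j]] * 5), 1, tolerance = 1e-9)
  ## raw angles follow the sin(theta)/2 law (KS test)
  ks <- suppressWarnings(stats::ks.test(
    ai$angles * pi / 180, function(q) (1 - cos(q)) / 2))
  expect_gt(ks$p.value, 0.01)
  ## empty distance bins are flagged, not NaN-filled
  ae <- angleDistribution(iso$trajectory, 1, iso$truth$probes,
                          c(0, 0.5, 13), angleBin = 5)
  expect_true(ae$empty[1])
  expect_null(ae$density[[1]])
})

test_that("hydrogen-bond counting matches textbook geometry and the
           brute-force oracle", {
  box <- c(50, 50, 50)
  ## ideal linear dimer at 2.8 A, H on the O-O axis
  co <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.3, 0.9, 0),
              c(2.8, 0, 0), c(3.7, 0.2, 0), c(2.5, 0.9, 0))
  w <- data.frame(o = c(1, 4), h1 = c(2, 5), h2 = c(3, 6))
  expect_equal(countHBonds(co, box, w, w$o)$count, 1L)
  ## beyond the distance cutoff: no bond
  co2 <- co
  co2[4:6, 1] <- co2[4:6, 1] + 2.2
  expect_equal(countHBonds(co2, box, w, w$o)$count, 0L)
  ## hand-built 5-water cluster with mixed geometries vs brute force
  set.seed(41)
  for (rep in 1:5) {
    oo <- matrix(runif(15, 10, 16), ncol = 3)
    coords <- NULL
    for (i in 1:5) {
      d1 <- stats::rnorm(3); d1 <- d1 / sqrt(sum(d1^2))
      d2 <- stats::rnorm(3); d2 <- d2 / sqrt(sum(d2^2))
      coords <- rbind(coords, oo[i, ], oo[i, ] + 0.96 * d1,
                      oo[i, ] + 0.96 * d2)
    }
    w5 <- data.frame(o = seq(1, 13, by = 3), h1 = seq(2, 14, by = 3),
                     h2 = seq(3, 15, by = 3))
    expect_equal(countHBonds(coords, box, w5, w5$o)$count,
                 bruteForceHBonds(coords, box, w5))
  }
  ## lattice generator truth
  lt <- makeTrajectory("lattice", nFrames = 1, nSide = 4, spacing = 2.8,
                       seed = 42)
  hb <- countHBonds(frameCoords(lt$trajectory, 1),
                    boxLengths(lt$trajectory), lt$truth$waters,
                    lt$truth$waters$o)
  expect_equal(hb$count, lt$truth$hbonds)
  ## missing hydrogens are a validation error
  wbad <- data.frame(o = c(1, 4), h1 = c(NA, 5), h2 = c(3, 6))
  expect_error(countHBonds(co, box, wbad, wbad$o), "without attached H")
})

test_that("shell statistics reproduce the constructed truth and boundary
           convention", {
  fx <- shellFixture()
  tr <- Trajectory(fx$coords, fx$box)
  st <- shellHBondStats(tr, fx$solute, fx$waters, shellCutoff = 4)
  expect_equal(st$shellMean, fx$shellMean)
  expect_equal(st$bulkMean, fx$bulkMean)
  ## distance exactly at the cutoff is inside the shell (closed interval)
  d0 <- sqrt(sum((fx$coords[1, ] - fx$coords[fx$solute, ])^2))
  st2 <- shellHBondStats(tr, fx$solute, fx$waters, shellCutoff = d0)
  expect_gte(st2$perFrame$nShell[1], 1L)
  expect_error(shellHBondStats(tr, integer(0), fx$waters), "no solute")
  ## far-away cutoff empties the shell
  expect_error(shellHBondStats(tr, fx$solute, fx$waters,
                               shellCutoff = 1e-3), "empty")
})

test_that("analyses are invariant under translation and rewrapping", {
  ig <- makeTrajectory("ideal_gas", box = 12, nFrames = 10, nAtoms = 150,
                       seed = 51)
  tr <- ig$trajectory
  shift <- c(3.7, -1.2, 5.5)
  co2 <- lapply(tr@coords, function(x) {
    y <- sweep(x, 2, shift, `+`)
    y - rep(12, 3)[col(y)] * floor(y / 12)
  })
  tr2 <- Trajectory(co2, c(12, 12, 12), tr@elements)
  r1 <- rdfAroundCenter(tr, 1, 2:150, rMax = 4, binWidth = 0.5)
  r2 <- rdfAroundCenter(tr2, 1, 2:150, rMax = 4, binWidth = 0.5)
  expect_equal(r1$g, r2$g, tolerance = 1e-9)

  fx <- shellFixture()
  co <- fx$coords + 17.3
  co <- co - 40 * floor(co / 40)
  st <- shellHBondStats(Trajectory(co, fx$box), fx$solute, fx$waters, 4)
  expect_equal(st$shellMean, 2)
  expect_equal(st$bulkMean, 3)
})

test_that("XYZ and GRO trajectories read back correctly", {
  tj <- makeTrajectory("ideal_gas", box = c(12, 14, 16), nFrames = 3,
                       nAtoms = 25, seed = 61)$trajectory
  p <- tempfile(fileext = ".xyz")
  writeXYZ(tj, p)
  back <- readXYZ(p)
  expect_equal(nFrames(back), 3)
  expect_lt(max(abs(frameCoords(back, 2) - frameCoords(tj, 2))), 1e-9)
  expect_equal(boxLengths(back, 1), c(12, 14, 16))

  ## minimal two-frame GRO file (nm units)
  gro <- c("frame 1", "2",
           "    1SOL     OW    1   0.100   0.200   0.300",
           "    1SOL    HW1    2   0.150   0.250   0.350",
           "   2.00000   2.00000   2.00000",
           "frame 2", "2",
           "    1SOL     OW    1   0.110   0.210   0.310",
           "    1SOL    HW1    2   0.160   0.260   0.360",
           "   2.00000   2.00000   2.00000")
  pg <- tempfile(fileext = ".gro")
  writeLines(gro, pg)
  g <- readGRO(pg)
  expect_equal(nFrames(g), 2)
  expect_equal(frameCoords(g, 1)[1, ], c(1, 2, 3))
  expect_equal(boxLengths(g, 2), c(20, 20, 20))
  expect_identical(g@elements, c("O", "H"))
})
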