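## Shared fixtures and independent oracles for the test-suite. Everything is
## generated in code; no data files.

## Brute-force periodic geometric centre: enumerate all 27 images of every
## member atom and average the configuration that minimises the spread.
bruteForceCenter <- function(coords, box, indices) {
  ref <- coords[indices[1L], ]
  pts <- lapply(indices, function(i) {
    imgs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) %*% diag(box)
    sweep(imgs, 2, coords[i, ], `+`)
  })
  best <- vapply(seq_along(indices), function(k) {
    d2 <- rowSums(sweep(pts[[k]], 2, ref)^2)
    pts[[k]][which.min(d2), ]
  }, numeric(3))
  gc <- rowMeans(best)
  gc - box * floor(gc / box)
}

## Naive all-pairs hydrogen-bond count (independent of the package path).
bruteForceHBonds <- function(coords, box, waters, rMax = 3.5,
                             angleMax = 30) {
  mi <- function(d) d - box * round(d / box)
  n <- nrow(waters)
  count <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      oi <- waters$o[i]; oj <- waters$o[j]
      roo <- sqrt(sum(mi(coords[oj, ] - coords[oi, ])^2))
      if (roo > rMax) next
      bonded <- FALSE
      for (don in c(i, j)) {
        acc <- if (don == i) j else i
        od <- waters$o[don]; oa <- waters$o[acc]
        for (h in c(waters$h1[don], waters$h2[don])) {
          if (is.na(h)) next
          vh <- mi(coords[h, ] - coords[od, ])
          va <- mi(coords[oa, ] - coords[od, ])
          ang <- acos(min(max(sum(vh * va) /
                                sqrt(sum(vh^2) * sum(va^2)), -1), 1)) *
            180 / pi
          if (ang <= angleMax) bonded <- TRUE
        }
      }
      if (bonded) count <- count + 1L
    }
  }
  count
}

## A constructed configuration: four shell waters in a square ring (each
## takes part in exactly two water-water H-bonds), four bulk waters in a K4
## tetrahedron (three bonds each), and one solute atom at the ring centre.
shellFixture <- function() {
  mkwater <- function(o, d1, d2) rbind(o, o + 0.96 * d1, o + 0.96 * d2)
  sq <- list(c(0, 0, 0), c(2.8, 0, 0), c(2.8, 2.8, 0), c(0, 2.8, 0))
  coords <- NULL
  for (i in 1:4) {
    nxt <- sq[[i %% 4 + 1]]
    d1 <- nxt - sq[[i]]
    d1 <- d1 / sqrt(sum(d1^2))
    coords <- rbind(coords, mkwater(sq[[i]], d1, c(0, 0, 1)))
  }
  ## K4 graph: donations 1->2, 1->3, 2->4, 2->3, 3->4, 4->1 cover all six
  ## unordered pairs with at most two donated hydrogens per water
  v <- rbind(c(0, 0, 0), c(2.8, 0, 0), c(1.4, 2.42487, 0),
             c(1.4, 0.80829, 2.28619)) + 15
  don <- list(c(2, 3), c(4, 3), c(4, NA), c(1, NA))
  for (i in 1:4) {
    ds <- don[[i]]
    d1 <- v[ds[1], ] - v[i, ]
    d1 <- d1 / sqrt(sum(d1^2))
    d2 <- if (is.na(ds[2])) c(0, 0, -1) else {
      t <- v[ds[2], ] - v[i, ]
      t / sqrt(sum(t^2))
    }
    coords <- rbind(coords, mkwater(v[i, ], d1, d2))
  }
  solute <- nrow(coords) + 1L
  coords <- rbind(coords, c(1.4, 1.4, 0))
  list(coords = coords, box = c(40, 40, 40), solute = solute,
       waters = data.frame(o = seq(1, 22, by = 3), h1 = seq(2, 23, by = 3),
                           h2 = seq(3, 24, by = 3)),
       shellMean = 2, bulkMean = 3)
}

## Random feasible small instance for the decomposition optimality oracle.
randomLPInstance <- function(seed) {
  set.seed(seed)
  g <- seq(2300, 2700, length.out = 60)
  mk <- function() pmax(pseudoVoigt(g, runif(1, 2350, 2650),
                                    runif(1, 60, 160), runif(1, 5, 30),
                                    runif(1, 0, 0.3)) - runif(1, 0.1, 0.5),
                        0)
  epsP <- mk(); epsO <- mk()
  x <- runif(1, 0.2, 0.8)
  NP <- runif(1, 2, 8); NO <- runif(1, 1, 5)
  wp <- runif(1); wo <- runif(1)
  extra <- mk() * runif(1, 0, 0.5)
  a <- (1 - x) * NP; b <- x * NO
  C <- wp * a * epsP + wo * b * epsO + extra
  NExp <- runif(1, 2, 6)
  list(grid = g, epsP = epsP, epsO = epsO, x = x, NP = NP, NO = NO,
       NExp = NExp, C = C, a = a, b = b)
}
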