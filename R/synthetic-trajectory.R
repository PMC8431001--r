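## Toy trajectories with known ground truth for the solvation-shell
## analyses: uniform (ideal-gas) points, fixed-radius shells, H-bonded
## water lattices, and oriented diatomic-probe ensembles.

#' Generate a ground-truthed toy trajectory
#'
#' Placement rules:
#' \describe{
#'   \item{`ideal_gas`}{`nAtoms` points uniform in the box each frame;
#'     the RDF around any reference converges to 1.}
#'   \item{`fixed_radius_shell`}{a tagged centre atom (index 1) plus `k`
#'     atoms at exactly distance `d` in random directions each frame.}
#'   \item{`lattice`}{an `nSide^3` cubic lattice of waters with spacing
#'     `spacing`; every water donates its two hydrogens towards the +x and
#'     +y neighbours, so with periodic wrapping the water-water hydrogen
#'     bond count is exactly `2 * nSide^3` and every water takes part in 4
#'     bonds.}
#'   \item{`oriented_osmolytes`}{a target atom (index 1) at the box centre
#'     plus `nProbes` diatomic probes (reference atom + bond-end atom,
#'     bond length `bondLength`) at uniform random distances in
#'     `distanceRange` from the target; bond orientations follow `law`:
#'     `"aligned"` (pointing exactly at the target: all angles 0) or
#'     `"isotropic"` (uniform on the sphere: angle density
#'     `sin(theta)/2`).}
#' }
#'
#' All randomness flows from `seed`; the same seed reproduces the trajectory
#' exactly. The returned truth record is machine-readable and consumed by
#' the test-suite.
#'
#' @param rule placement rule, see above.
#' @param box orthorhombic box lengths (length-3 or scalar).
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @param nAtoms,k,d,nSide,spacing,nProbes,bondLength,distanceRange,law
#'   rule-specific parameters.
#' @return List with `trajectory` ([Trajectory-class]) and `truth` (list of
#'   the generating parameters, including the seed).
#' @export
makeTrajectory <- function(rule = c("ideal_gas", "fixed_radius_shell",
                                    "lattice", "oriented_osmolytes"),
                           box = 20, nFrames = 100, seed = 1,
                           nAtoms = 1000, k = 12, d = 3.0, nSide = 4,
                           spacing = 2.8, nProbes = 500, bondLength = 1.2,
                           distanceRange = NULL,
                           law = c("isotropic", "aligned")) {
  rule <- match.arg(rule)
  law <- match.arg(law)
  box <- rep_len(as.numeric(box), 3L)
  stopifnot(all(box > 0), nFrames > 0)
  set.seed(seed)
  randUnit <- function(n) {
    ## uniform directions on the sphere
    z <- stats::rnorm(3 * n)
    m <- matrix(z, ncol = 3)
    m / sqrt(rowSums(m^2))
  }
  truth <- list(rule = rule, box = box, nFrames = nFrames, seed = seed)
  if (rule == "ideal_gas") {
    stopifnot(nAtoms > 0)
    coords <- lapply(seq_len(nFrames), function(i) {
      cbind(stats::runif(nAtoms, 0, box[1]), stats::runif(nAtoms, 0, box[2]),
            stats::runif(nAtoms, 0, box[3]))
    })
    el <- rep("Ar", nAtoms)
    truth$nAtoms <- nAtoms
  } else if (rule == "fixed_radius_shell") {
    stopifnot(k > 0, d > 0, d < min(box) / 2)
    centre <- box / 2
    coords <- lapply(seq_len(nFrames), function(i) {
      sh <- sweep(randUnit(k) * d, 2, centre, `+`)
      rbind(centre, sh)
    })
    el <- c("X", rep("O", k))
    truth$k <- k
    truth$d <- d
    truth$center <- 1L
    truth$shell <- seq.int(2L, k + 1L)
  } else if (rule == "lattice") {
    stopifnot(nSide > 1, spacing > 0)
    box <- rep(nSide * spacing, 3L)
    g <- (seq_len(nSide) - 1) * spacing + spacing / 2
    o <- as.matrix(expand.grid(x = g, y = g, z = g))
    dimnames(o) <- NULL
    nW <- nrow(o)
    oh <- 0.96
    x1 <- o; x1[, 1] <- x1[, 1] + oh            # H towards +x neighbour
    x2 <- o; x2[, 2] <- x2[, 2] + oh            # H towards +y neighbour
    frame <- rbind(o, x1, x2)
    coords <- rep(list(frame), nFrames)
    el <- c(rep("O", nW), rep("H", 2 * nW))
    truth$nWaters <- nW
    truth$spacing <- spacing
    truth$waters <- data.frame(o = seq_len(nW), h1 = nW + seq_len(nW),
                               h2 = 2 * nW + seq_len(nW))
    ## with periodic wrapping each water donates 2 bonds
    truth$hbonds <- if (spacing <= 3.5) 2L * nW else 0L
    truth$bondsPerWater <- if (spacing <= 3.5) 4 else 0
  } else {  # oriented_osmolytes
    stopifnot(nProbes > 0, bondLength > 0)
    centre <- box / 2
    if (is.null(distanceRange)) distanceRange <- c(2, min(box) / 2 - 2)
    stopifnot(distanceRange[1] > 0, distanceRange[2] > distanceRange[1])
    coords <- lapply(seq_len(nFrames), function(i) {
      rr <- stats::runif(nProbes, distanceRange[1], distanceRange[2])
      ref <- sweep(randUnit(nProbes) * rr, 2, centre, `+`)
      dir <- if (law == "aligned") {
        v <- sweep(-ref, 2, -centre)            # centre - ref
        v / sqrt(rowSums(v^2))
      } else {
        randUnit(nProbes)
      }
      ends <- ref + dir * bondLength
      rbind(centre, .wrapIntoBox(ref, box), .wrapIntoBox(ends, box))
    })
    el <- c("X", rep("C", nProbes), rep("O", nProbes))
    truth$nProbes <- nProbes
    truth$law <- law
    truth$bondLength <- bondLength
    truth$distanceRange <- distanceRange
    truth$target <- 1L
    truth$probes <- cbind(ref = 1L + seq_len(nProbes),
                          end = 1L + nProbes + seq_len(nProbes))
  }
  list(trajectory = Trajectory(coords, box, el), truth = truth)
}
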