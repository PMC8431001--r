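## Solvation-shell statistics from orthorhombic-box trajectories:
## fragment-centred radial distribution functions, distance-binned
## orientation-angle distributions, and geometric hydrogen-bond counts.
## Minimum-image convention throughout; atom indices are 1-based.

#' Geometric centre of a fragment under periodic boundaries
#'
#' Unweighted mean of the member coordinates after minimum-image unwrapping
#' relative to the fragment's first atom, wrapped back into the box. A
#' fragment whose unwrapped extent exceeds half the box in any direction is
#' ambiguous and raises an error.
#'
#' @param coords n_atoms x 3 coordinate matrix (Angstrom).
#' @param box box lengths (length-3).
#' @param indices atom indices of the fragment (1-based).
#' @return Length-3 numeric: the geometric centre, inside the box.
#' @export
geometricCenter <- function(coords, box, indices) {
  if (!length(indices)) stop("empty fragment")
  if (any(indices < 1L) || any(indices > nrow(coords)))
    stop("fragment indices out of range")
  ref <- coords[indices[1L], ]
  d <- .minImage(sweep(coords[indices, , drop = FALSE], 2, ref), box)
  ext <- apply(d, 2, function(v) max(v) - min(v))
  if (any(ext > box / 2))
    stop("ambiguous fragment: unwrapped extent exceeds half the box")
  .wrapIntoBox(ref + colMeans(d), box)
}

#' Radial distribution function around a fragment geometric centre
#'
#' Histograms minimum-image distances from the fragment's geometric centre
#' to the selection atoms, frame by frame, and normalises by ideal-gas
#' counting: `g(bin) = (V / N) * count / (n_frames * V_shell)` with
#' `V_shell = (4 pi / 3)(r+^3 - r-^3)`, i.e. the estimator of
#' `g(r) = (V/N) dN/dV`. The returned `gSE` column is the Poisson standard
#' error `g / sqrt(count)`.
#'
#' @param traj a [Trajectory-class].
#' @param fragment atom indices defining the reference fragment.
#' @param selection atom indices whose distribution is analysed (non-empty,
#'   disjoint from the fragment for a meaningful result).
#' @param rMax histogram range (Angstrom); must not exceed half the
#'   smallest box length. Default: `0.49 *` smallest box length.
#' @param binWidth bin width (Angstrom), default 0.1.
#' @return data.frame with columns `r` (bin centres), `g`, `count`, `gSE`;
#'   attributes `binWidth`, `V`, `N`, `nFrames`.
#' @export
rdfAroundCenter <- function(traj, fragment, selection, rMax = NULL,
                            binWidth = 0.1) {
  stopifnot(methods::is(traj, "Trajectory"))
  if (!length(selection)) stop("empty selection")
  Lmin <- min(traj@box)
  if (is.null(rMax)) rMax <- 0.49 * Lmin
  if (rMax > Lmin / 2 + 1e-9)
    stop(sprintf("rMax (%.2f A) exceeds half the smallest box length (%.2f A)",
                 rMax, Lmin / 2))
  edges <- seq(0, rMax, by = binWidth)
  if (edges[length(edges)] < rMax) edges <- c(edges, rMax)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  vols <- numeric(nFrames(traj))
  for (i in seq_len(nFrames(traj))) {
    x <- traj@coords[[i]]
    L <- traj@box[i, ]
    gc <- geometricCenter(x, L, fragment)
    d <- .minImage(sweep(x[selection, , drop = FALSE], 2, gc), L)
    r <- sqrt(rowSums(d^2))
    r <- r[r < rMax]
    counts <- counts + tabulate(findInterval(r, edges,
                                             rightmost.closed = TRUE),
                                nbins = nb)
    vols[i] <- prod(L)
  }
  V <- mean(vols)
  N <- length(selection)
  vShell <- (4 * pi / 3) * (edges[-1]^3 - edges[-(nb + 1L)]^3)
  g <- (V / N) * counts / (nFrames(traj) * vShell)
  gSE <- ifelse(counts > 0, g / sqrt(counts), NA_real_)
  out <- data.frame(r = (edges[-1] + edges[-(nb + 1L)]) / 2, g = g,
                    count = counts, gSE = gSE)
  attr(out, "binWidth") <- binWidth
  attr(out, "V") <- V
  attr(out, "N") <- N
  attr(out, "nFrames") <- nFrames(traj)
  out
}

#' Distance-binned orientation-angle distributions
#'
#' For every probe molecule and frame, computes the angle between the
#' probe's bond vector (e.g. the C=O bond of urea or the N-O bond of TMAO)
#' and the vector from the probe's reference atom to the fragment geometric
#' centre, both under minimum image. Angles are accumulated into the probe's
#' GC-distance bin and each distance bin's histogram is normalised to unit
#' area over degrees.
#'
#' @param traj a [Trajectory-class].
#' @param fragment atom indices of the reference fragment.
#' @param probes two-column matrix of atom indices `(reference, bond end)`,
#'   one row per probe; the bond vector runs reference -> bond end.
#' @param distanceBins ascending distance bin edges (Angstrom).
#' @param angleBin angle bin width in degrees (default 5).
#' @param keepAngles logical: also return the raw angles and distances
#'   (useful for distributional tests); default `FALSE`.
#' @return List with `angle` (bin centres, degrees), `distanceBins`,
#'   `density` (list of unit-area densities per distance bin; `NULL` where a
#'   bin is empty), `counts` (observations per distance bin), `empty`
#'   (logical), and `skipped` (zero-length bond vectors encountered); with
#'   `keepAngles` also `angles` and `distances`.
#' @export
angleDistribution <- function(traj, fragment, probes, distanceBins,
                              angleBin = 5, keepAngles = FALSE) {
  stopifnot(methods::is(traj, "Trajectory"))
  probes <- as.matrix(probes)
  if (ncol(probes) != 2L) stop("probes must be a two-column index matrix")
  if (any(probes[, 1] == probes[, 2]))
    stop("bond vectors need two distinct atoms")
  if (is.unsorted(distanceBins, strictly = TRUE))
    stop("distance bins must be strictly ascending")
  aEdges <- seq(0, 180, by = angleBin)
  if (aEdges[length(aEdges)] < 180) aEdges <- c(aEdges, 180)
  nA <- length(aEdges) - 1L
  nD <- length(distanceBins) - 1L
  H <- matrix(0, nrow = nD, ncol = nA)
  skipped <- 0L
  rawTheta <- if (keepAngles) vector("list", nFrames(traj)) else NULL
  rawDist <- if (keepAngles) vector("list", nFrames(traj)) else NULL
  for (i in seq_len(nFrames(traj))) {
    x <- traj@coords[[i]]
    L <- traj@box[i, ]
    gc <- geometricCenter(x, L, fragment)
    v1 <- .minImage(x[probes[, 2], , drop = FALSE] -
                      x[probes[, 1], , drop = FALSE], L)
    v2 <- -.minImage(sweep(x[probes[, 1], , drop = FALSE], 2, gc), L)
    n1 <- sqrt(rowSums(v1^2))
    n2 <- sqrt(rowSums(v2^2))
    ok <- n1 > 1e-9 & n2 > 1e-9
    skipped <- skipped + sum(!ok)
    cosang <- rowSums(v1 * v2)[ok] / (n1[ok] * n2[ok])
    theta <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    db <- findInterval(n2[ok], distanceBins, rightmost.closed = TRUE)
    ab <- findInterval(theta, aEdges, rightmost.closed = TRUE)
    keep <- db >= 1L & db <= nD
    for (k in which(keep)) H[db[k], ab[k]] <- H[db[k], ab[k]] + 1
    if (keepAngles) {
      rawTheta[[i]] <- theta[keep]
      rawDist[[i]] <- n2[ok][keep]
    }
  }
  if (skipped > 0L)
    warning(skipped, " zero-length bond vectors skipped")
  counts <- rowSums(H)
  dens <- vector("list", nD)
  for (j in seq_len(nD)) {
    if (counts[j] > 0) dens[[j]] <- H[j, ] / (counts[j] * angleBin)
  }
  out <- list(angle = (aEdges[-1] + aEdges[-(nA + 1L)]) / 2,
              distanceBins = distanceBins, density = dens, counts = counts,
              empty = counts == 0, skipped = skipped)
  if (keepAngles) {
    out$angles <- unlist(rawTheta)
    out$distances <- unlist(rawDist)
  }
  out
}

#' Geometric hydrogen-bond criteria
#'
#' Defaults: donor-acceptor O..O distance at most 3.5 Angstrom and
#' H-O(donor)..O(acceptor) angle at most 30 degrees - standard literature
#' choices; both are configurable and are echoed into every result that uses
#' them.
#'
#' @param rMax maximum O..O distance, Angstrom.
#' @param angleMax maximum H-O..O angle at the donor, degrees.
#' @return Named list with `rMax` and `angleMax`.
#' @export
hbondCriteria <- function(rMax = 3.5, angleMax = 30) {
  stopifnot(rMax > 0, angleMax > 0)
  list(rMax = rMax, angleMax = angleMax)
}

#' Count geometric hydrogen bonds in one frame
#'
#' A donor-acceptor pair is bonded when the O..O distance is within
#' `criteria$rMax` and the angle between the donor O->H and donor O->
#' acceptor O vectors is within `criteria$angleMax`, under minimum image.
#' Each unordered oxygen pair is counted at most once (symmetric
#' double-counting excluded).
#'
#' @param coords n_atoms x 3 coordinate matrix.
#' @param box box lengths.
#' @param donors data.frame with columns `o`, `h1`, `h2` (atom indices; `h2`
#'   may be `NA` for single-H donors).
#' @param acceptors oxygen atom indices.
#' @param criteria from [hbondCriteria()].
#' @return List with `count` and `pairs` (two-column matrix of bonded oxygen
#'   index pairs, donor first).
#' @export
countHBonds <- function(coords, box, donors, acceptors,
                        criteria = hbondCriteria()) {
  if (!all(c("o", "h1") %in% names(donors)))
    stop("donors must have columns o and h1 (optionally h2)")
  if (is.null(donors$h2)) donors$h2 <- NA_integer_
  if (any(is.na(donors$h1)))
    stop("donor without attached H position")
  cosMax <- cos(criteria$angleMax * pi / 180)
  pairs <- NULL
  seen <- character(0)
  for (k in seq_len(nrow(donors))) {
    od <- donors$o[k]
    hs <- stats::na.omit(c(donors$h1[k], donors$h2[k]))
    acc <- setdiff(acceptors, od)
    if (!length(acc)) next
    dOO <- .minImage(sweep(coords[acc, , drop = FALSE], 2, coords[od, ]),
                     box)
    rOO <- sqrt(rowSums(dOO^2))
    near <- which(rOO <= criteria$rMax)
    for (j in near) {
      oa <- acc[j]
      key <- paste(min(od, oa), max(od, oa))
      if (key %in% seen) next
      for (h in hs) {
        vh <- .minImage(coords[h, ] - coords[od, ], box)
        ca <- sum(vh * dOO[j, ]) / (sqrt(sum(vh^2)) * rOO[j])
        if (ca >= cosMax - 1e-12) {
          pairs <- rbind(pairs, c(od, oa))
          seen <- c(seen, key)
          break
        }
      }
    }
  }
  list(count = if (is.null(pairs)) 0L else nrow(pairs),
       pairs = if (is.null(pairs)) matrix(integer(0), ncol = 2) else pairs,
       criteria = criteria)
}

#' Water-water hydrogen bonds per shell and bulk water
#'
#' Classifies waters by the minimum-image distance of their oxygen to the
#' nearest solute heavy atom (at most `shellCutoff`, closed interval ->
#' shell; otherwise bulk reference) and reports the mean number of
#' water-water hydrogen bonds a shell water and a bulk water participate in,
#' averaged over frames, with per-frame values and variances.
#'
#' @param traj a [Trajectory-class].
#' @param solute atom indices of the solute heavy atoms (disjoint from the
#'   water atoms).
#' @param waters data.frame with columns `o`, `h1`, `h2` (atom indices).
#' @param shellCutoff shell cutoff, Angstrom (default 4.0).
#' @param criteria hydrogen-bond criteria, from [hbondCriteria()].
#' @return List with `shellMean`, `bulkMean`, `perFrame` (data.frame with
#'   per-frame means and water counts), `shellVar`, `bulkVar`, `shellCutoff`
#'   and `criteria`.
#' @export
shellHBondStats <- function(traj, solute, waters, shellCutoff = 4.0,
                            criteria = hbondCriteria()) {
  stopifnot(methods::is(traj, "Trajectory"), shellCutoff > 0)
  if (!length(solute)) stop("no solute atoms given")
  watAtoms <- c(waters$o, waters$h1, waters$h2)
  if (length(intersect(solute, stats::na.omit(watAtoms))))
    stop("solute and water selections must be disjoint")
  pf <- data.frame(frame = seq_len(nFrames(traj)), shellMean = NA_real_,
                   bulkMean = NA_real_, nShell = 0L, nBulk = 0L)
  for (i in seq_len(nFrames(traj))) {
    x <- traj@coords[[i]]
    L <- traj@box[i, ]
    dmin <- vapply(waters$o, function(o) {
      d <- .minImage(sweep(x[solute, , drop = FALSE], 2, x[o, ]), L)
      sqrt(min(rowSums(d^2)))
    }, numeric(1))
    inShell <- dmin <= shellCutoff
    hb <- countHBonds(x, L, waters, waters$o, criteria)
    deg <- tabulate(match(c(hb$pairs[, 1], hb$pairs[, 2]), waters$o),
                    nbins = nrow(waters))
    pf$nShell[i] <- sum(inShell)
    pf$nBulk[i] <- sum(!inShell)
    if (any(inShell)) pf$shellMean[i] <- mean(deg[inShell])
    if (any(!inShell)) pf$bulkMean[i] <- mean(deg[!inShell])
  }
  if (all(pf$nShell == 0L))
    stop("empty solvation shell in every frame")
  list(shellMean = mean(pf$shellMean, na.rm = TRUE),
       bulkMean = mean(pf$bulkMean, na.rm = TRUE),
       perFrame = pf,
       shellVar = stats::var(pf$shellMean[!is.na(pf$shellMean)]),
       bulkVar = stats::var(pf$bulkMean[!is.na(pf$bulkMean)]),
       shellCutoff = shellCutoff, criteria = criteria)
}
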