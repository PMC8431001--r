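## Band-shape parameters and the transform of OD-stretch bands into
## oxygen-oxygen distance distributions P(R_OO).

#' Band-shape parameters of a single dominant band
#'
#' Computes the position at maximum (parabolic-refined argmax), the gravity
#' centre (intensity-weighted mean wavenumber, related to the mean hydrogen
#' bond energy), the full width at half height (linear interpolation of the
#' half-maximum crossings) and the integrated intensity (trapezoid rule).
#'
#' @param s a [Spectrum-class] with a positive peak.
#' @return Named list `nu_max`, `nu_grav`, `fwhh`, `intensity`.
#' @export
bandParameters <- function(s) {
  stopifnot(methods::is(s, "Spectrum"))
  x <- s@grid; y <- s@values
  if (max(y) <= 0) stop("band parameters need a positive peak")
  pk <- .parabolicArgmax(x, y)
  intensity <- .trapz(x, y)
  nuGrav <- .trapz(x, x * y) / intensity
  w <- .fwhh(x, y)
  list(nu_max = pk$x, nu_grav = nuGrav, fwhh = w$width,
       intensity = intensity)
}

#' Build a frequency-distance map from a knot table
#'
#' The empirical correlation between the OD stretching frequency and the
#' O..O distance of the donor-acceptor pair is supplied as a knot table
#' (Angstrom vs cm-1, frequency strictly increasing with distance) and
#' interpolated by a monotone (Hyman-filtered) cubic spline in both
#' directions. Queries outside the knot span are clamped and flagged via the
#' `clamped` attribute of the returned functions' environment.
#'
#' @param knots data.frame with columns `R_angstrom` and `nu_cm1`.
#' @return A [FrequencyDistanceMap-class].
#' @export
frequencyDistanceMap <- function(knots) {
  stopifnot(is.data.frame(knots),
            all(c("R_angstrom", "nu_cm1") %in% names(knots)))
  knots <- knots[order(knots$R_angstrom), c("R_angstrom", "nu_cm1")]
  if (any(diff(knots$R_angstrom) <= 0) || any(diff(knots$nu_cm1) <= 0))
    stop("calibration knots must be strictly monotone ",
         "(nu increasing with R)")
  fNu <- stats::splinefun(knots$R_angstrom, knots$nu_cm1, method = "hyman")
  fR <- stats::splinefun(knots$nu_cm1, knots$R_angstrom, method = "hyman")
  rRange <- range(knots$R_angstrom)
  nuRange <- range(knots$nu_cm1)
  nuOfR <- function(r) fNu(pmin(pmax(r, rRange[1]), rRange[2]))
  rOfNu <- function(nu) fR(pmin(pmax(nu, nuRange[1]), nuRange[2]))
  dnuDr <- function(r) fNu(pmin(pmax(r, rRange[1]), rRange[2]), deriv = 1)
  methods::new("FrequencyDistanceMap", knots = knots, nuOfR = nuOfR,
               rOfNu = rOfNu, dnuDr = dnuDr)
}

#' The bundled default OD frequency / O..O distance calibration
#'
#' Loads the synthetic monotone knot table shipped with the package
#' (`inst/extdata/synthetic_od_oo_calibration.csv`). It is assembled to
#' follow the slope and range of published ice/hydrate-type correlations and
#' is intended as a replaceable placeholder: absolute distances in any
#' output depend on the calibration used, which is therefore always recorded
#' in reports.
#'
#' @return A [FrequencyDistanceMap-class].
#' @export
defaultFrequencyDistanceMap <- function() {
  path <- system.file("extdata", "synthetic_od_oo_calibration.csv",
                      package = "hydroshell", mustWork = TRUE)
  knots <- utils::read.csv(path, comment.char = "#")
  m <- frequencyDistanceMap(knots)
  m
}

setMethod("show", "FrequencyDistanceMap", function(object) {
  cat(sprintf(
    "FrequencyDistanceMap: %d knots, R %.3f..%.3f A, nu %.0f..%.0f cm-1\n",
    nrow(object@knots), min(object@knots$R_angstrom),
    max(object@knots$R_angstrom), min(object@knots$nu_cm1),
    max(object@knots$nu_cm1)))
})

#' Transform a band into an O..O distance distribution
#'
#' Change of variables through the frequency-distance correlation:
#' `P(R) = eps(nu(R)) |d nu / d R| / Z`, normalised to unit area on the
#' distance grid. Small negative intensities (noise) are clipped to zero
#' within `delta` and the clipped intensity fraction is recorded in the
#' result metadata. The distance grid covers the overlap of the map range
#' and the spectrum support.
#'
#' @param s a non-negative (within `delta`) [Spectrum-class].
#' @param map a [FrequencyDistanceMap-class].
#' @param rStep distance grid spacing in Angstrom (default 0.001).
#' @param delta clipping tolerance for negative intensities.
#' @return A [DistanceDistribution-class] with mode `rMode` (R deg, the most
#'   likely O..O distance) and mean `rMean`.
#' @export
toDistanceDistribution <- function(s, map, rStep = 0.001, delta = 1e-6) {
  stopifnot(methods::is(s, "Spectrum"),
            methods::is(map, "FrequencyDistanceMap"))
  y <- s@values
  neg <- y < 0
  clippedFrac <- 0
  if (any(neg)) {
    if (any(y < -max(delta, 0) - 1e-12))
      warning("intensities below -delta clipped in distance transform")
    clippedFrac <- -sum(y[neg]) / max(sum(abs(y)), .Machine$double.eps)
    y[neg] <- 0
  }
  rLo <- map@rOfNu(max(min(s@grid), min(map@knots$nu_cm1)))
  rHi <- map@rOfNu(min(max(s@grid), max(map@knots$nu_cm1)))
  if (rHi - rLo < rStep)
    stop("no overlap between the band support and the calibration domain")
  rGrid <- seq(rLo, rHi, by = rStep)
  nu <- map@nuOfR(rGrid)
  f <- stats::splinefun(s@grid, y, method = "natural")
  eps <- pmax(f(nu), 0)
  jac <- abs(map@dnuDr(rGrid))
  dens <- eps * jac
  Z <- .trapz(rGrid, dens)
  if (Z <= 0)
    stop("band and calibration domain have all-zero overlap")
  dens <- dens / Z
  ## renormalise exactly after clipping round-off
  dens <- dens / .trapz(rGrid, dens)
  pk <- .parabolicArgmax(rGrid, dens)
  rMean <- .trapz(rGrid, rGrid * dens)
  methods::new("DistanceDistribution", rGrid = rGrid, density = dens,
               rMode = pk$x, rMean = rMean,
               meta = list(clippedFraction = clippedFrac, rStep = rStep))
}

#' Difference of two distance distributions
#'
#' Resamples both unit-area distributions onto the common (overlapping)
#' grid and returns `P1 - P2`. When the overlap covers both supports the
#' difference integrates to 0 (within 1e-6).
#'
#' @param p1,p2 [DistanceDistribution-class] objects with overlapping grids.
#' @return data.frame with columns `r` (Angstrom) and `delta` (1/Angstrom).
#' @export
deltaP <- function(p1, p2) {
  stopifnot(methods::is(p1, "DistanceDistribution"),
            methods::is(p2, "DistanceDistribution"))
  lo <- max(min(p1@rGrid), min(p2@rGrid))
  hi <- min(max(p1@rGrid), max(p2@rGrid))
  if (hi <= lo) stop("distance grids do not overlap")
  step <- min(stats::median(diff(p1@rGrid)), stats::median(diff(p2@rGrid)))
  r <- seq(lo, hi, by = step)
  f1 <- stats::splinefun(p1@rGrid, p1@density, method = "natural")
  f2 <- stats::splinefun(p2@rGrid, p2@density, method = "natural")
  data.frame(r = r, delta = f1(r) - f2(r))
}

#' Accessors for distance distributions
#'
#' @param object a [DistanceDistribution-class].
#' @name distance-accessors
NULL

#' @rdname distance-accessors
#' @export
setMethod("distanceGrid", "DistanceDistribution",
          function(object) object@rGrid)

#' @rdname distance-accessors
#' @export
setMethod("distanceDensity", "DistanceDistribution",
          function(object) object@density)

#' @rdname distance-accessors
#' @export
setMethod("distanceMode", "DistanceDistribution",
          function(object) object@rMode)

#' @rdname distance-accessors
#' @export
setMethod("distanceMean", "DistanceDistribution",
          function(object) object@rMean)

setMethod("show", "DistanceDistribution", function(object) {
  cat(sprintf(
    "DistanceDistribution: R %.3f..%.3f A, mode %.3f A, mean %.3f A\n",
    min(object@rGrid), max(object@rGrid), object@rMode, object@rMean))
})

#' @rdname distance-accessors
#' @param x a [DistanceDistribution-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature("DistanceDistribution", "missing"),
          function(x, y, ...) {
  args <- list(...)
  if (is.null(args$xlab)) args$xlab <- expression(R[OO] ~ (ring(A)))
  if (is.null(args$ylab)) args$ylab <- expression(P(R[OO]) ~ (ring(A)^-1))
  if (is.null(args$type)) args$type <- "l"
  do.call(graphics::plot, c(list(x@rGrid, x@density), args))
  invisible(NULL)
})
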