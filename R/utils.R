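## Internal numeric helpers shared across modules.

## Trapezoid integral on a (possibly non-uniform) grid.
.trapz <- function(x, y) pracma::trapz(x, y)

## Parabolic refinement of an argmax through the point and its two
## neighbours; falls back to the grid point at the ends of the grid.
.parabolicArgmax <- function(x, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) {
    return(list(x = x[i], y = y[i]))
  }
  x0 <- x[i - 1L]; x1 <- x[i]; x2 <- x[i + 1L]
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  denom <- (y0 - 2 * y1 + y2)
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * max(abs(y1), 1)) {
    return(list(x = x1, y = y1))
  }
  ## uniform-spacing parabola in the local index coordinate
  h1 <- x1 - x0; h2 <- x2 - x1
  ## general three-point parabola vertex
  a <- (y2 - y1) / h2 - (y1 - y0) / h1
  a <- a / (h1 + h2)
  b <- (y2 - y1) / h2 - a * h2
  if (abs(a) < .Machine$double.eps) return(list(x = x1, y = y1))
  xv <- x1 - b / (2 * a)
  yv <- y1 + b * (xv - x1) + a * (xv - x1)^2
  ## keep the vertex inside the bracket
  if (xv < x0 || xv > x2) return(list(x = x1, y = y1))
  list(x = xv, y = yv)
}

## Full width at half height by linear interpolation of half-maximum
## crossings. Returns the width and the crossing positions used. With more
## than two crossings the outermost pair is used and a warning is raised.
.fwhh <- function(x, y) {
  ymax <- max(y)
  half <- ymax / 2
  d <- y - half
  s <- which(d[-1] * d[-length(d)] < 0)
  cross <- vapply(s, function(i) {
    x[i] + (x[i + 1L] - x[i]) * (half - y[i]) / (y[i + 1L] - y[i])
  }, numeric(1))
  cross <- c(cross, x[d == 0])
  cross <- sort(unique(cross))
  if (length(cross) < 2L) {
    stop("band does not cross its half height twice inside the window")
  }
  if (length(cross) > 2L) {
    warning("ambiguous band: more than two half-height crossings; ",
            "using the outermost pair")
  }
  list(width = max(cross) - min(cross), lo = min(cross), hi = max(cross))
}

## Savitzky-Golay smoothing of a signal plus the matching pointwise
## standard-error propagation (the filter is linear, so variances combine
## with squared coefficients). window = 0 disables smoothing.
.sgSmooth <- function(y, window, order = 3L) {
  if (window <= 1L) return(y)
  window <- .oddify(min(window, length(y) - (1 - length(y) %% 2)))
  if (window <= order + 1L) return(y)
  signal::sgolayfilt(y, p = order, n = window)
}

.sgSmoothSE <- function(se, window, order = 3L) {
  if (window <= 1L) return(se)
  window <- .oddify(min(window, length(se) - (1 - length(se) %% 2)))
  if (window <= order + 1L) return(se)
  fm <- signal::sgolay(p = order, n = window)
  coef <- fm[(window + 1L) %/% 2L, ]
  v <- stats::filter(se^2, coef^2, sides = 2)
  v <- as.numeric(v)
  ## edges: fall back to the unsmoothed standard error
  v[!is.finite(v)] <- se[!is.finite(v)]^2
  sqrt(pmax(v, 0))
}

.oddify <- function(n) {
  n <- as.integer(n)
  if (n %% 2L == 0L) n - 1L else n
}

## Minimum-image displacement(s) in an orthorhombic box. `d` is a vector or
## an n x 3 matrix of raw displacements, `box` the three box lengths.
.minImage <- function(d, box) {
  if (is.matrix(d)) {
    sweep(d, 2, box, function(x, L) x - L * round(x / L))
  } else {
    d - box * round(d / box)
  }
}

.wrapIntoBox <- function(x, box) {
  if (is.matrix(x)) {
    sweep(x, 2, box, function(v, L) v - L * floor(v / L))
  } else {
    x - box * floor(x / box)
  }
}

#' Molality implied by a solute/water molecule count
#'
#' Converts a molecule count ratio, as used when composing a simulation box,
#' into a molality. For example, three osmolyte molecules dissolved among
#' 4035 water molecules correspond to `3 / (4035 * 0.018015)` ~= 0.041 mol
#' per kg of water.
#'
#' @param nSolute number of solute molecules.
#' @param nWater number of water molecules.
#' @param M molar mass of water in kg/mol (default 0.018015).
#' @return Molality in mol solute per kg water.
#' @examples
#' molalityFromCounts(3, 4035)
#' @export
molalityFromCounts <- function(nSolute, nWater, M = 0.018015) {
  stopifnot(nSolute >= 0, nWater > 0, M > 0)
  nSolute / (nWater * M)
}
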