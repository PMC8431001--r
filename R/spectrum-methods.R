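## Accessors, show/plot methods and the elementary spectrum operations.

#' Spectrum accessors
#'
#' @param object a [Spectrum-class].
#' @return `wavenumbers`: the cm-1 grid; `intensities`: the intensity
#'   values; `spectrumRole`: the role string; `spectrumMeta`: the metadata
#'   list.
#' @name Spectrum-accessors
NULL

#' @rdname Spectrum-accessors
#' @export
setMethod("wavenumbers", "Spectrum", function(object) object@grid)

#' @rdname Spectrum-accessors
#' @export
setMethod("intensities", "Spectrum", function(object) object@values)

#' @rdname Spectrum-accessors
#' @export
setMethod("spectrumRole", "Spectrum", function(object) object@role)

#' @rdname Spectrum-accessors
#' @export
setMethod("spectrumMeta", "Spectrum", function(object) object@meta)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum [%s]: %d points, %.1f..%.1f cm-1\n",
              object@role, length(object@grid), min(object@grid),
              max(object@grid)))
  cat(sprintf("  intensity range: %.4g .. %.4g\n",
              min(object@values), max(object@values)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

#' @describeIn Spectrum-accessors number of grid points.
#' @export
setMethod("length", "Spectrum", function(x) length(x@grid))

#' Plot a spectrum
#'
#' @param x a [Spectrum-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature("Spectrum", "missing"), function(x, y, ...) {
  args <- list(...)
  if (is.null(args$xlab)) args$xlab <- expression(tilde(nu) ~ (cm^-1))
  if (is.null(args$ylab)) args$ylab <- x@role
  if (is.null(args$type)) args$type <- "l"
  do.call(graphics::plot, c(list(x@grid, x@values), args))
  invisible(NULL)
})

#' Convert absorbance to molar absorptivity
#'
#' Beer-Lambert conversion `epsilon = A / (c_HDO * d)` with the path length
#' `d` given in um (converted internally to cm) and the HDO molarity in
#' mol/dm3, yielding molar absorptivity in dm3 mol-1 cm-1.
#'
#' @param s a [Spectrum-class] with role `"absorbance"`.
#' @param pathLength cell path length in um (> 0).
#' @param cHDO HDO molarity in mol/dm3 (> 0).
#' @return A [Spectrum-class] with role `"molar_absorptivity"`.
#' @examples
#' s <- Spectrum(2200:2230, rep(0.5, 31))
#' e <- toMolarAbsorptivity(s, pathLength = 28.4, cHDO = 0.5)
#' @export
toMolarAbsorptivity <- function(s, pathLength, cHDO) {
  stopifnot(methods::is(s, "Spectrum"))
  if (pathLength <= 0) stop("path length must be > 0")
  if (cHDO <= 0) stop("HDO molarity must be > 0")
  dCm <- pathLength * 1e-4
  meta <- s@meta
  meta$pathLength_um <- pathLength
  meta$hdoMolarity <- cHDO
  methods::new("Spectrum", grid = s@grid, values = s@values / (cHDO * dCm),
               role = "molar_absorptivity", meta = meta)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Cubic-spline interpolation onto `grid`, which must lie inside the source
#' grid span (no extrapolation). The role is preserved.
#'
#' @param s a [Spectrum-class].
#' @param grid target wavenumbers (cm-1), ascending.
#' @return A [Spectrum-class] on `grid`.
#' @export
resampleSpectrum <- function(s, grid) {
  stopifnot(methods::is(s, "Spectrum"))
  grid <- as.numeric(grid)
  if (min(grid) < min(s@grid) - 1e-9 || max(grid) > max(s@grid) + 1e-9)
    stop("target grid extends beyond the source spectrum span ",
         sprintf("(%.2f..%.2f vs %.2f..%.2f cm-1)", min(grid), max(grid),
                 min(s@grid), max(s@grid)))
  f <- stats::splinefun(s@grid, s@values, method = "natural")
  methods::new("Spectrum", grid = grid, values = f(grid), role = s@role,
               meta = s@meta)
}

#' Scale a spectrum to unit maximum
#'
#' Divides the intensities by their maximum so that the output peaks at 1,
#' as used when overlaying band shapes for comparison.
#'
#' @param s a [Spectrum-class] with a positive maximum.
#' @return The rescaled [Spectrum-class].
#' @export
scaleToMax <- function(s) {
  stopifnot(methods::is(s, "Spectrum"))
  m <- max(s@values)
  if (m <= 0) stop("cannot scale a spectrum with non-positive maximum")
  methods::new("Spectrum", grid = s@grid, values = s@values / m,
               role = s@role, meta = s@meta)
}

#' Uniform analysis grid
#'
#' The canonical internal grid: 1 cm-1 spacing over the analysis window,
#' default 2200..2800 cm-1 (the OD stretch region). All series are resampled
#' onto it before pointwise arithmetic.
#'
#' @param window length-2 numeric, window limits in cm-1.
#' @param step grid spacing in cm-1.
#' @return Numeric vector of wavenumbers.
#' @export
analysisGrid <- function(window = c(2200, 2800), step = 1) {
  stopifnot(length(window) == 2L, window[2] > window[1], step > 0)
  seq(window[1], window[2], by = step)
}
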