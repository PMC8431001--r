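## S4 class definitions.

.spectrumRoles <- c("absorbance", "molar_absorptivity", "affected",
                    "theoretical", "shared_excess")

#' Spectrum: intensity values on a wavenumber grid
#'
#' The basic container for mid-IR spectra. `grid` holds wavenumbers in
#' cm-1 (strictly ascending), `values` either a dimensionless absorbance or a
#' molar absorptivity in dm3 mol-1 cm-1, depending on `role`. `meta` carries
#' free-form provenance such as temperature (deg C), path length (um), the
#' affected number N, or pointwise standard errors.
#'
#' @slot grid numeric, wavenumbers in cm-1, strictly increasing.
#' @slot values numeric intensities, same length as `grid`, finite.
#' @slot role one of `"absorbance"`, `"molar_absorptivity"`, `"affected"`,
#'   `"theoretical"`, `"shared_excess"`.
#' @slot meta named list of provenance items.
#' @aliases Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
  representation(grid = "numeric", values = "numeric", role = "character",
                 meta = "list"),
  prototype(role = "absorbance", meta = list()))

setValidity("Spectrum", function(object) {
  msg <- NULL
  if (length(object@grid) != length(object@values))
    msg <- c(msg, "grid and values must have the same length")
  if (length(object@grid) < 2L)
    msg <- c(msg, "a spectrum needs at least 2 points")
  if (any(!is.finite(object@grid)) || any(!is.finite(object@values)))
    msg <- c(msg, "grid and values must be finite")
  if (length(object@grid) >= 2L && any(diff(object@grid) <= 0))
    msg <- c(msg, "grid must be strictly increasing")
  if (length(object@role) != 1L || !object@role %in% .spectrumRoles)
    msg <- c(msg, paste("role must be one of:",
                        paste(.spectrumRoles, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Construct a Spectrum
#'
#' A strictly descending grid (as written by many instruments) is reversed;
#' duplicated wavenumbers are an error.
#'
#' @param grid wavenumbers in cm-1.
#' @param values intensities, same length as `grid`.
#' @param role spectrum role; see [Spectrum-class].
#' @param meta named list of provenance items.
#' @return A [Spectrum-class] object.
#' @examples
#' s <- Spectrum(2200:2210, exp(-(2200:2210 - 2205)^2 / 8))
#' @export
Spectrum <- function(grid, values, role = "absorbance", meta = list()) {
  grid <- as.numeric(grid)
  values <- as.numeric(values)
  if (length(grid) >= 2L && all(diff(grid) < 0)) {
    grid <- rev(grid)
    values <- rev(values)
  }
  if (anyDuplicated(grid))
    stop("duplicated wavenumbers in spectrum grid")
  if (is.unsorted(grid, strictly = TRUE))
    stop("spectrum grid is neither ascending nor descending")
  methods::new("Spectrum", grid = grid, values = values, role = role,
               meta = meta)
}

#' DerivativeSpectrum: d(epsilon)/dm at infinite dilution
#'
#' Result of the per-wavenumber weighted regression of a molar-absorptivity
#' concentration series against molality, with the intercept fixed at the
#' bulk spectrum. Under the two-state mixture model the slope equals
#' `N * M * (eps_a - eps_b)`.
#'
#' @slot grid wavenumbers, cm-1.
#' @slot slope d(epsilon)/dm at m -> 0, (dm3 mol-1 cm-1) / (mol kg-1).
#' @slot stderr pointwise standard error of the slope (>= 0).
#' @slot nPoints number of non-zero molalities in the series.
#' @aliases DerivativeSpectrum-class
#' @exportClass DerivativeSpectrum
setClass("DerivativeSpectrum",
  representation(grid = "numeric", slope = "numeric", stderr = "numeric",
                 nPoints = "integer"))

setValidity("DerivativeSpectrum", function(object) {
  msg <- NULL
  n <- length(object@grid)
  if (length(object@slope) != n || length(object@stderr) != n)
    msg <- c(msg, "grid, slope and stderr must have equal length")
  if (any(object@stderr < 0)) msg <- c(msg, "stderr must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' AffectedWaterResult: affected spectrum and affected number
#'
#' @slot epsilonA [Spectrum-class] of solute-affected water (role
#'   `"affected"`).
#' @slot N affected-water number (moles of affected water per mole of
#'   solute), > 0.
#' @slot M mean molar mass of water, kg/mol.
#' @slot tolerance negativity tolerance delta (molar-absorptivity units)
#'   effectively applied during N determination.
#' @slot stderr pointwise standard error of `epsilonA` propagated from the
#'   series regression.
#' @slot diagnostics list: `minEpsilonA`, `residualRMS`, `smoothWindow`,
#'   `nAuto` (logical: was N determined automatically).
#' @aliases AffectedWaterResult-class
#' @exportClass AffectedWaterResult
setClass("AffectedWaterResult",
  representation(epsilonA = "Spectrum", N = "numeric", M = "numeric",
                 tolerance = "numeric", stderr = "numeric",
                 diagnostics = "list"))

setValidity("AffectedWaterResult", function(object) {
  msg <- NULL
  if (object@N <= 0) msg <- c(msg, "N must be > 0")
  if (object@M <= 0) msg <- c(msg, "M must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' TernaryDecomposition: shared/excess water decomposition
#'
#' Output of [decomposeSharedExcess()]: the theoretical (non-interacting)
#' affected spectrum, the affected-number difference `deltaN`, the retained
#' fractions of pure-solute affected water, and the shared/excess remainder.
#'
#' @slot epsTheor theoretical affected spectrum (role `"theoretical"`).
#' @slot NTheor theoretical affected number `(1-x) N_p + x N_o`.
#' @slot deltaN `N_exp - N_theor`.
#' @slot wP,wO retained fractions of peptide- and osmolyte-affected water,
#'   each in `[0, 1]`.
#' @slot epsShared shared/excess spectrum (role `"shared_excess"`), per mole
#'   of shared/excess water.
#' @slot NShared water count attributed to the shared/excess population.
#' @slot sharePct integrated-intensity share (%) of the shared/excess
#'   component in the experimental affected spectrum.
#' @slot label `"shared"`, `"excess"` or `"none"`, from the sign of
#'   `deltaN` against its tolerance.
#' @slot delta non-negativity tolerance used by the solver (intensity units).
#' @aliases TernaryDecomposition-class
#' @exportClass TernaryDecomposition
setClass("TernaryDecomposition",
  representation(epsTheor = "Spectrum", NTheor = "numeric",
                 deltaN = "numeric", wP = "numeric", wO = "numeric",
                 epsShared = "Spectrum", NShared = "numeric",
                 sharePct = "numeric", label = "character",
                 delta = "numeric"))

setValidity("TernaryDecomposition", function(object) {
  msg <- NULL
  if (object@wP < -1e-12 || object@wP > 1 + 1e-12)
    msg <- c(msg, "wP must lie in [0, 1]")
  if (object@wO < -1e-12 || object@wO > 1 + 1e-12)
    msg <- c(msg, "wO must lie in [0, 1]")
  if (object@sharePct < -1e-6 || object@sharePct > 100 + 1e-6)
    msg <- c(msg, "sharePct must lie in [0, 100]")
  if (!object@label %in% c("shared", "excess", "none"))
    msg <- c(msg, "label must be shared, excess or none")
  if (is.null(msg)) TRUE else msg
})

#' FrequencyDistanceMap: monotone OD-frequency vs O..O-distance correlation
#'
#' A knot table (R in Angstrom, nu in cm-1, nu strictly increasing with R)
#' with monotone cubic (Hyman-filtered) interpolants in both directions and
#' the Jacobian d(nu)/dR along the curve.
#'
#' @slot knots data.frame with columns `R_angstrom`, `nu_cm1`.
#' @slot nuOfR,rOfNu,dnuDr interpolating functions.
#' @aliases FrequencyDistanceMap-class
#' @exportClass FrequencyDistanceMap
setClass("FrequencyDistanceMap",
  representation(knots = "data.frame", nuOfR = "function", rOfNu = "function",
                 dnuDr = "function"))

#' DistanceDistribution: P(R_OO) on a distance grid
#'
#' @slot rGrid distances in Angstrom, ascending.
#' @slot density P(R_OO) in 1/Angstrom, non-negative, unit area.
#' @slot rMode most likely O..O distance (parabolic-refined argmax).
#' @slot rMean mean O..O distance.
#' @slot meta list: clipped negative-intensity fraction, calibration id, ...
#' @aliases DistanceDistribution-class
#' @exportClass DistanceDistribution
setClass("DistanceDistribution",
  representation(rGrid = "numeric", density = "numeric", rMode = "numeric",
                 rMean = "numeric", meta = "list"),
  prototype(meta = list()))

setValidity("DistanceDistribution", function(object) {
  msg <- NULL
  if (length(object@rGrid) != length(object@density))
    msg <- c(msg, "rGrid and density must have equal length")
  if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
  area <- pracma::trapz(object@rGrid, object@density)
  if (abs(area - 1) > 1e-6)
    msg <- c(msg, sprintf("density must integrate to 1 (got %.8f)", area))
  rng <- range(object@rGrid)
  if (object@rMode < rng[1] || object@rMode > rng[2] ||
      object@rMean < rng[1] || object@rMean > rng[2])
    msg <- c(msg, "rMode and rMean must lie inside the rGrid span")
  if (is.null(msg)) TRUE else msg
})

#' SeriesManifest: a concentration series of spectra
#'
#' Describes an HDO difference-spectra concentration series: one bulk
#' (m = 0) reference spectrum plus at least three distinct non-zero
#' molalities, with the solute composition (mole fractions among solutes
#' only; water excluded), the cell path length, temperature, and the HDO
#' molarity of each solution (required input: how the HDO molarity follows
#' from the D2O dosing is not derivable here).
#'
#' @slot entries data.frame with columns `file`, `molality`, `hdoMolarity`.
#' @slot composition named numeric vector of solute mole fractions (sum 1).
#' @slot bulkFile path of the bulk HDO spectrum.
#' @slot bulkHdoMolarity HDO molarity of the bulk solution, mol/dm3.
#' @slot pathLength path length in um.
#' @slot temperature temperature in deg C.
#' @slot dir directory that `file` entries are relative to.
#' @aliases SeriesManifest-class
#' @exportClass SeriesManifest
setClass("SeriesManifest",
  representation(entries = "data.frame", composition = "numeric",
                 bulkFile = "character", bulkHdoMolarity = "numeric",
                 pathLength = "numeric", temperature = "numeric",
                 dir = "character"),
  prototype(temperature = 25, dir = "."))

setValidity("SeriesManifest", function(object) {
  msg <- NULL
  e <- object@entries
  need <- c("file", "molality", "hdoMolarity")
  if (!all(need %in% names(e)))
    msg <- c(msg, "entries must have columns file, molality, hdoMolarity")
  else {
    if (any(e$molality < 0)) msg <- c(msg, "molalities must be >= 0")
    nz <- unique(e$molality[e$molality > 0])
    if (length(nz) < 3L)
      msg <- c(msg, "need at least 3 distinct non-zero molalities")
  }
  if (abs(sum(object@composition) - 1) > 1e-8)
    msg <- c(msg, "solute mole fractions must sum to 1")
  if (object@pathLength <= 0) msg <- c(msg, "path length must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Trajectory: coordinates and orthorhombic boxes per frame
#'
#' @slot coords list of n_atoms x 3 numeric matrices (Angstrom), one per
#'   frame; the atom count is constant across frames.
#' @slot box n_frames x 3 matrix of orthorhombic box lengths (Angstrom).
#' @slot elements character vector of atom labels.
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory",
  representation(coords = "list", box = "matrix", elements = "character"))

setValidity("Trajectory", function(object) {
  msg <- NULL
  if (length(object@coords) == 0L) msg <- c(msg, "no frames")
  nat <- vapply(object@coords, nrow, integer(1))
  if (length(unique(nat)) > 1L)
    msg <- c(msg, "atom count must be constant across frames")
  if (nrow(object@box) != length(object@coords) || ncol(object@box) != 3L)
    msg <- c(msg, "box must be an n_frames x 3 matrix")
  if (any(object@box <= 0)) msg <- c(msg, "box lengths must be positive")
  if (length(object@elements) != nat[1])
    msg <- c(msg, "elements must have one label per atom")
  if (is.null(msg)) TRUE else msg
})

#' Construct a Trajectory
#'
#' @param coords list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param box orthorhombic box lengths: either a length-3 vector (constant
#'   box) or an n_frames x 3 matrix.
#' @param elements atom labels; defaults to `"X"`.
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(coords, box, elements = NULL) {
  if (is.matrix(coords)) coords <- list(coords)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  if (!is.matrix(box)) {
    box <- matrix(rep(as.numeric(box), each = length(coords)),
                  nrow = length(coords), ncol = 3)
  }
  if (is.null(elements)) elements <- rep("X", nrow(coords[[1]]))
  methods::new("Trajectory", coords = coords, box = box,
               elements = as.character(elements))
}
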