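## Ground-truthed synthetic HDO spectra series obeying the two-state
## bulk/affected mixture model, for end-to-end validation of the extraction
## and decomposition machinery.

#' Pseudo-Voigt band profile
#'
#' `eta * Lorentzian + (1 - eta) * Gaussian`, both parameterised by the same
#' full width at half height and unit peak height, scaled by `amplitude`.
#'
#' @param nu wavenumbers (cm-1).
#' @param center band position (cm-1).
#' @param fwhh full width at half height (cm-1, > 0).
#' @param amplitude peak height.
#' @param eta Lorentzian fraction in `[0, 1]`.
#' @return Numeric vector of intensities.
#' @export
pseudoVoigt <- function(nu, center, fwhh, amplitude = 1, eta = 0) {
  stopifnot(fwhh > 0, eta >= 0, eta <= 1)
  sg <- fwhh / (2 * sqrt(2 * log(2)))
  gam <- fwhh / 2
  g <- exp(-(nu - center)^2 / (2 * sg^2))
  l <- gam^2 / ((nu - center)^2 + gam^2)
  amplitude * (eta * l + (1 - eta) * g)
}

#' Band specification for the synthetic generators
#'
#' @param center,fwhh,amplitude,eta as in [pseudoVoigt()].
#' @return A named list (one band component).
#' @export
bandSpec <- function(center, fwhh, amplitude, eta = 0) {
  stopifnot(fwhh > 0, amplitude > 0)
  list(center = center, fwhh = fwhh, amplitude = amplitude, eta = eta)
}

#' Evaluate a (possibly zero-anchored) composite band on a grid
#'
#' Sums the pseudo-Voigt components and, when `clip > 0`, subtracts
#' `clip * max` and floors at zero. The clipped form has exact zeros in the
#' far wings, mimicking affected-water bands that vanish inside the analysis
#' window - the feature that makes the affected number N identifiable by the
#' non-negativity criterion.
#'
#' @param grid wavenumbers (cm-1).
#' @param components list of [bandSpec()] components.
#' @param clip wing-clipping fraction of the band maximum (default 0: none).
#' @return Numeric vector of intensities.
#' @export
buildBand <- function(grid, components, clip = 0) {
  if (!length(components)) stop("no band components")
  if (!is.null(components$center)) components <- list(components)
  v <- rowSums(vapply(components, function(b) {
    pseudoVoigt(grid, b$center, b$fwhh, b$amplitude, b$eta)
  }, numeric(length(grid))))
  if (clip > 0) v <- pmax(v - clip * max(v), 0)
  v
}

#' Spectral ground truth for the binary-series generator
#'
#' Bundles the bulk band, the affected band components, the affected number
#' and the relative noise level. The defaults emulate an HDO OD-stretch
#' study: a bulk band at 2509 cm-1 with fwhh 162 cm-1 (amplitude chosen so
#' the integrated intensity is ~1e4 dm3 mol-1 cm-2), and clipped affected
#' bands so that the affected spectrum vanishes on part of the window.
#'
#' @param N affected number (moles affected water per mole solute, > 0).
#' @param components list of [bandSpec()] affected-band components.
#' @param bulk a [bandSpec()] for the bulk band.
#' @param noise relative (multiplicative) Gaussian noise level.
#' @param clip wing-clipping fraction for the affected band.
#' @return A list of class `"spectralTruth"`.
#' @export
spectralTruth <- function(N,
                          components = list(bandSpec(2460, 150, 30, 0.15),
                                            bandSpec(2540, 120, 12, 0.10)),
                          bulk = bandSpec(2509, 162, 58.3, 0),
                          noise = 0, clip = 0.02) {
  stopifnot(N > 0, noise >= 0, clip >= 0, clip < 1)
  structure(list(N = N, components = components, bulk = bulk,
                 noise = noise, clip = clip),
            class = "spectralTruth")
}

#' Default peptide-like and osmolyte-like spectral truths
#'
#' Convenience presets: a peptide-like solute with N = 6 and a
#' two-component affected band red-shifted against bulk, and an
#' osmolyte-like solute (urea-like) with N = 2.7 and a slightly blue-shifted
#' band. Used by examples and tests; all parameters are overridable.
#'
#' @param noise relative noise level.
#' @return A `spectralTruth` list.
#' @export
peptideTruth <- function(noise = 0) spectralTruth(6, noise = noise)

#' @rdname peptideTruth
#' @export
osmolyteTruth <- function(noise = 0) {
  spectralTruth(2.7, components = list(bandSpec(2520, 140, 35, 0.10)),
                noise = noise)
}

#' Generate a binary concentration series from a spectral truth
#'
#' Builds `eps(nu; m) = (1 - N M m) eps_b + N M m eps_a` for each molality,
#' applies multiplicative Gaussian noise `(1 + sigma z)` to the non-zero
#' molality members (the bulk reference is treated as noise-free, as it is
#' in practice measured with far higher effective signal-to-noise), and
#' returns the series together with a machine-readable truth record. With
#' `dir` set, the series is also written to disk as absorbance CSV files
#' plus a YAML manifest (inverting the Beer-Lambert conversion with the
#' given path length and HDO molarity).
#'
#' @param truth a [spectralTruth()].
#' @param molalities non-zero molalities, mol/kg.
#' @param seed RNG seed (recorded in the truth record).
#' @param grid analysis grid; default [analysisGrid()].
#' @param M molar mass of water, kg/mol.
#' @param dir optional output directory for CSV + manifest files.
#' @param pathLength,cHDO Beer-Lambert parameters used only when writing.
#' @return List with `spectra`, `molalities`, `bulk`, `epsA` (the true
#'   affected spectrum), `truth` (parameters + seed), and - when `dir` is
#'   given - `manifest` (path of the YAML manifest).
#' @export
makeBinarySeries <- function(truth, molalities = seq(0.5, 2.5, by = 0.5),
                             seed = 1, grid = analysisGrid(), M = 0.018015,
                             dir = NULL, pathLength = 28.4, cHDO = 0.5) {
  stopifnot(inherits(truth, "spectralTruth"), all(molalities > 0))
  if (truth$N * M * max(molalities) >= 1)
    stop("affected fraction N*M*m reaches 1; reduce N or the molalities")
  set.seed(seed)
  epsB <- buildBand(grid, list(truth$bulk))
  epsA <- buildBand(grid, truth$components, clip = truth$clip)
  bulk <- methods::new("Spectrum", grid = grid, values = epsB,
                       role = "molar_absorptivity",
                       meta = list(molality = 0))
  spectra <- lapply(molalities, function(m) {
    v <- (1 - truth$N * M * m) * epsB + truth$N * M * m * epsA
    if (truth$noise > 0)
      v <- v * (1 + truth$noise * stats::rnorm(length(v)))
    methods::new("Spectrum", grid = grid, values = v,
                 role = "molar_absorptivity", meta = list(molality = m))
  })
  rec <- list(kind = "binary", N = truth$N, M = M, noise = truth$noise,
              clip = truth$clip, seed = seed, molalities = molalities,
              bulk = truth$bulk, components = truth$components)
  out <- list(spectra = spectra, molalities = molalities, bulk = bulk,
              epsA = methods::new("Spectrum", grid = grid, values = epsA,
                                  role = "affected",
                                  meta = list(N = truth$N)),
              truth = rec)
  if (!is.null(dir)) out$manifest <- .writeSeries(out, dir, pathLength, cHDO)
  out
}

## Write a generated series to disk as absorbance CSVs + YAML manifest +
## truth record; returns the manifest path.
.writeSeries <- function(series, dir, pathLength, cHDO,
                         composition = c(solute = 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dCm <- pathLength * 1e-4
  toAbs <- function(s) methods::new("Spectrum", grid = s@grid,
                                    values = s@values * cHDO * dCm,
                                    role = "absorbance")
  files <- sprintf("solution_%02d.csv", seq_along(series$spectra))
  for (i in seq_along(series$spectra)) {
    writeSpectrum(toAbs(series$spectra[[i]]), file.path(dir, files[i]))
  }
  writeSpectrum(toAbs(series$bulk), file.path(dir, "bulk.csv"))
  man <- seriesManifest(files, series$molalities, composition,
                        bulkFile = "bulk.csv", hdoMolarity = cHDO,
                        pathLength = pathLength, dir = dir)
  path <- file.path(dir, "series.yaml")
  writeManifest(man, path)
  yaml::write_yaml(series$truth, file.path(dir, "truth.yaml"))
  path
}

#' Shared/excess water count for a target intensity share
#'
#' Inverts the share bookkeeping of the ternary construction: given the
#' target integrated-intensity share (%) of the shared/excess component in
#' the experimental affected spectrum, returns the shared water count
#' `N_sh = share/(100 - share) * [w_p (1-x) N_p I_p + w_o x N_o I_o] / I_sh`
#' where `I` are the integrated intensities of the component bands.
#'
#' @param sharePct target share in percent, in `(0, 100)`.
#' @param truthP,truthO [spectralTruth()] objects of the pure solutes.
#' @param sharedComponents list of [bandSpec()] for the shared band.
#' @param x osmolyte mole fraction among solutes.
#' @param wP,wO retained fractions of pure-solute affected water.
#' @param grid analysis grid.
#' @param clip wing-clipping fraction of the shared band.
#' @return The shared water count `N_sh`.
#' @export
sharedCountForShare <- function(sharePct, truthP, truthO, sharedComponents,
                                x, wP = 1, wO = 1, grid = analysisGrid(),
                                clip = 0.02) {
  stopifnot(sharePct > 0, sharePct < 100)
  ip <- .trapz(grid, buildBand(grid, truthP$components, clip = truthP$clip))
  io <- .trapz(grid, buildBand(grid, truthO$components, clip = truthO$clip))
  ish <- .trapz(grid, buildBand(grid, sharedComponents, clip = clip))
  pure <- wP * (1 - x) * truthP$N * ip + wO * x * truthO$N * io
  sharePct / (100 - sharePct) * pure / ish
}

#' Generate a ternary (peptide + osmolyte) concentration series
#'
#' The implied experimental affected spectrum is
#' `eps_exp = [w_p (1-x) N_p eps_p + w_o x N_o eps_o + N_sh eps_sh] / N_exp`
#' with `N_exp = w_p (1-x) N_p + w_o x N_o + N_sh`, and the series is then
#' synthesised from it through the two-state mixture model at the given
#' solute-pair molalities. `N_sh = 0` with `w_p = w_o = 1` reproduces the
#' non-interacting (theoretical) construction exactly.
#'
#' @param truthP,truthO [spectralTruth()] objects of the pure solutes.
#' @param x osmolyte mole fraction among solutes.
#' @param shared optional list `list(components = list(bandSpec(...)), N =
#'   N_sh, clip = 0.02)` describing the shared/excess water band.
#' @param wP,wO retained fractions in `[0, 1]`.
#' @param molalities solute-pair molalities, mol/kg.
#' @param seed RNG seed.
#' @param noise relative noise applied to the mixture series (defaults to
#'   `truthP$noise`).
#' @param grid analysis grid.
#' @param M molar mass of water, kg/mol.
#' @param dir optional output directory (CSV + manifest, as in
#'   [makeBinarySeries()]).
#' @return List with the mixture `spectra`, `molalities`, `bulk`, the true
#'   component spectra (`epsP`, `epsO`, `epsShared`, `epsExp`), `NExp`, and
#'   the `truth` record.
#' @export
makeTernarySeries <- function(truthP, truthO, x, shared = NULL, wP = 1,
                              wO = 1, molalities = seq(0.5, 2.5, by = 0.5),
                              seed = 1, noise = truthP$noise,
                              grid = analysisGrid(), M = 0.018015,
                              dir = NULL) {
  stopifnot(inherits(truthP, "spectralTruth"),
            inherits(truthO, "spectralTruth"),
            x >= 0, x <= 1, wP >= 0, wP <= 1, wO >= 0, wO <= 1)
  set.seed(seed)
  epsB <- buildBand(grid, list(truthP$bulk))
  epsP <- buildBand(grid, truthP$components, clip = truthP$clip)
  epsO <- buildBand(grid, truthO$components, clip = truthO$clip)
  NSh <- 0
  epsSh <- numeric(length(grid))
  if (!is.null(shared)) {
    NSh <- shared$N
    stopifnot(NSh >= 0)
    epsSh <- buildBand(grid, shared$components,
                       clip = shared$clip %||% 0.02)
  }
  NExp <- wP * (1 - x) * truthP$N + wO * x * truthO$N + NSh
  if (NExp <= 0) stop("degenerate construction: N_exp = 0")
  cExp <- wP * (1 - x) * truthP$N * epsP + wO * x * truthO$N * epsO +
    NSh * epsSh
  epsExp <- cExp / NExp
  if (NExp * M * max(molalities) >= 1)
    stop("affected fraction reaches 1; reduce the molalities")
  bulk <- methods::new("Spectrum", grid = grid, values = epsB,
                       role = "molar_absorptivity",
                       meta = list(molality = 0))
  spectra <- lapply(molalities, function(m) {
    v <- (1 - NExp * M * m) * epsB + NExp * M * m * epsExp
    if (noise > 0) v <- v * (1 + noise * stats::rnorm(length(v)))
    methods::new("Spectrum", grid = grid, values = v,
                 role = "molar_absorptivity", meta = list(molality = m))
  })
  mk <- function(v, role, meta = list()) {
    methods::new("Spectrum", grid = grid, values = v, role = role,
                 meta = meta)
  }
  ish <- .trapz(grid, NSh * epsSh)
  iexp <- .trapz(grid, NExp * epsExp)
  rec <- list(kind = "ternary", x = x, wP = wP, wO = wO, NP = truthP$N,
              NO = truthO$N, NSh = NSh, NExp = NExp, M = M, noise = noise,
              seed = seed, molalities = molalities,
              sharePct = if (iexp > 0) 100 * ish / iexp else 0)
  out <- list(spectra = spectra, molalities = molalities, bulk = bulk,
              epsP = mk(epsP, "affected", list(N = truthP$N)),
              epsO = mk(epsO, "affected", list(N = truthO$N)),
              epsShared = mk(epsSh, "shared_excess", list(N = NSh)),
              epsExp = mk(epsExp, "affected", list(N = NExp)),
              NExp = NExp, truth = rec)
  if (!is.null(dir)) {
    out$manifest <- .writeSeries(out, dir, pathLength = 28.4, cHDO = 0.5,
                                 composition = c(peptide = 1 - x,
                                                 osmolyte = x))
  }
  out
}
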