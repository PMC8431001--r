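## Series manifests (YAML) and series loading.

#' Construct a series manifest
#'
#' @param files spectrum files of the non-zero-molality solutions.
#' @param molalities molalities in mol solute per kg water, same length.
#' @param composition named numeric vector of solute mole fractions among
#'   solutes (water excluded); must sum to 1.
#' @param bulkFile file of the bulk (m = 0) HDO spectrum.
#' @param hdoMolarity HDO molarity (mol/dm3) of each solution; recycled.
#' @param bulkHdoMolarity HDO molarity of the bulk solution.
#' @param pathLength cell path length, um.
#' @param temperature temperature, deg C.
#' @param dir directory the file names are relative to.
#' @return A [SeriesManifest-class].
#' @export
seriesManifest <- function(files, molalities, composition, bulkFile,
                           hdoMolarity, bulkHdoMolarity = hdoMolarity[1],
                           pathLength = 28.4, temperature = 25, dir = ".") {
  entries <- data.frame(file = as.character(files),
                        molality = as.numeric(molalities),
                        hdoMolarity = rep_len(as.numeric(hdoMolarity),
                                              length(files)),
                        stringsAsFactors = FALSE)
  comp <- as.numeric(composition)
  names(comp) <- names(composition)
  methods::new("SeriesManifest", entries = entries, composition = comp,
               bulkFile = as.character(bulkFile),
               bulkHdoMolarity = as.numeric(bulkHdoMolarity),
               pathLength = as.numeric(pathLength),
               temperature = as.numeric(temperature), dir = dir)
}

#' Read or write a series manifest (YAML)
#'
#' The on-disk format has keys `bulk` (file), `bulk_hdo_molarity`,
#' `entries` (list of `{file, molality_mol_per_kg, composition}`),
#' `path_length_um`, `temperature_C` and `hdo_molarity` (one value per
#' entry). Compositions must agree across entries of one series.
#'
#' @param path manifest file.
#' @return [readManifest()]: a [SeriesManifest-class];
#'   [writeManifest()]: `path`, invisibly.
#' @export
readManifest <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- y$entries
  if (is.null(entries) || !length(entries)) stop("manifest has no entries")
  files <- vapply(entries, function(e) e$file, "")
  mol <- vapply(entries, function(e) as.numeric(e$molality_mol_per_kg),
                numeric(1))
  comp <- unlist(entries[[1]]$composition)
  hdo <- as.numeric(y$hdo_molarity)
  seriesManifest(files, mol, comp, bulkFile = y$bulk, hdoMolarity = hdo,
                 bulkHdoMolarity = as.numeric(y$bulk_hdo_molarity %||%
                                                hdo[1]),
                 pathLength = as.numeric(y$path_length_um %||% 28.4),
                 temperature = as.numeric(y$temperature_C %||% 25),
                 dir = dirname(path))
}

#' @rdname readManifest
#' @param manifest a [SeriesManifest-class].
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(methods::is(manifest, "SeriesManifest"))
  e <- manifest@entries
  y <- list(
    bulk = manifest@bulkFile,
    bulk_hdo_molarity = manifest@bulkHdoMolarity,
    path_length_um = manifest@pathLength,
    temperature_C = manifest@temperature,
    hdo_molarity = e$hdoMolarity,
    entries = lapply(seq_len(nrow(e)), function(i) {
      list(file = e$file[i], molality_mol_per_kg = e$molality[i],
           composition = as.list(manifest@composition))
    }))
  yaml::write_yaml(y, path)
  invisible(path)
}

setMethod("show", "SeriesManifest", function(object) {
  cat(sprintf("SeriesManifest: %d solutions + bulk, solutes: %s\n",
              nrow(object@entries),
              paste(sprintf("%s (x=%.2f)", names(object@composition),
                            object@composition), collapse = ", ")))
  cat(sprintf("  molalities: %s mol/kg; path %.1f um; %.1f degC\n",
              paste(format(object@entries$molality), collapse = ", "),
              object@pathLength, object@temperature))
})

#' Load a concentration series onto the analysis grid
#'
#' Reads all spectra of a manifest, converts absorbance to molar
#' absorptivity with the manifest path length and per-solution HDO molarity,
#' and resamples everything onto the common analysis grid.
#'
#' @param manifest a [SeriesManifest-class].
#' @param grid target wavenumber grid; default [analysisGrid()].
#' @return List with elements `spectra` (list of molar-absorptivity
#'   [Spectrum-class]), `molalities`, `bulk` (bulk spectrum) and
#'   `composition`.
#' @export
loadSeries <- function(manifest, grid = analysisGrid()) {
  stopifnot(methods::is(manifest, "SeriesManifest"))
  e <- manifest@entries
  readOne <- function(f, cHdo) {
    s <- readSpectrum(file.path(manifest@dir, f))
    if (s@role == "absorbance")
      s <- toMolarAbsorptivity(s, manifest@pathLength, cHdo)
    resampleSpectrum(s, grid)
  }
  spectra <- mapply(readOne, e$file, e$hdoMolarity, SIMPLIFY = FALSE)
  bulk <- readOne(manifest@bulkFile, manifest@bulkHdoMolarity)
  list(spectra = unname(spectra), molalities = e$molality, bulk = bulk,
       composition = manifest@composition)
}
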