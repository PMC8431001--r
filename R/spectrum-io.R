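## Reading and writing spectra: CSV (dialect `wavenumber_cm-1,value`) and a
## restricted JCAMP-DX profile (XYDATA=(X++(Y..Y)), AFFN form).

#' Read a spectrum from a text file
#'
#' Supports the package CSV dialect (header `wavenumber_cm-1,value`, comma
#' separator, '.' decimal) and JCAMP-DX files restricted to
#' `XYDATA=(X++(Y..Y))` with AFFN (plain decimal) values. A descending grid
#' is reversed on input; the role defaults to `"absorbance"` unless the file
#' header declares otherwise (CSV: a `# role: <role>` comment line; JCAMP:
#' `##YUNITS=` containing `MOLAR ABSORPTIVITY`).
#'
#' @param source path to the file.
#' @param format `"csv"` or `"jcamp"`; default guesses from the extension.
#' @return A [Spectrum-class].
#' @seealso [writeSpectrum()]
#' @export
readSpectrum <- function(source, format = c("auto", "csv", "jcamp")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", source, ignore.case = TRUE))
      "jcamp" else "csv"
  }
  if (!file.exists(source)) stop("no such file: ", source)
  switch(format, csv = .readSpectrumCSV(source),
         jcamp = .readSpectrumJCAMP(source))
}

.readSpectrumCSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  role <- "absorbance"
  comments <- grep("^#", lines, value = TRUE)
  rl <- grep("^#\\s*role:", comments, value = TRUE)
  if (length(rl)) role <- trimws(sub("^#\\s*role:", "", rl[1]))
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L) stop("malformed CSV (no data rows): ", path)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (trimws(header[1]) != "wavenumber_cm-1")
    stop("malformed CSV at line 1: expected header 'wavenumber_cm-1,value'")
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != 2L)
      stop(sprintf("malformed CSV at line %d of %s: expected 2 fields",
                   i + 1L, path))
  }
  x <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2L)))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop(sprintf("malformed CSV at line %d of %s: non-numeric value",
                 bad[1] + 1L, path))
  Spectrum(x, y, role = role)
}

#' Write a spectrum to a text file
#'
#' @param s a [Spectrum-class].
#' @param path output path.
#' @param format `"csv"` or `"jcamp"`.
#' @param title JCAMP title string.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(s, path, format = c("csv", "jcamp"),
                          title = "hydroshell spectrum") {
  stopifnot(methods::is(s, "Spectrum"))
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# role: %s", s@role), con)
    writeLines("wavenumber_cm-1,value", con)
    writeLines(sprintf("%.10g,%.10g", s@grid, s@values), con)
  } else {
    .writeSpectrumJCAMP(s, path, title)
  }
  invisible(path)
}

.writeSpectrumJCAMP <- function(s, path, title) {
  yunits <- if (s@role == "absorbance") "ABSORBANCE"
            else toupper(gsub("_", " ", s@role))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("##TITLE=%s", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    sprintf("##YUNITS=%s", yunits),
    "##XFACTOR=1.0",
    "##YFACTOR=1.0",
    sprintf("##FIRSTX=%.10g", s@grid[1]),
    sprintf("##LASTX=%.10g", s@grid[length(s@grid)]),
    sprintf("##NPOINTS=%d", length(s@grid)),
    "##XYDATA=(X++(Y..Y))"), con)
  ## one X plus up to 4 Y values per line, AFFN
  n <- length(s@grid)
  i <- 1L
  while (i <= n) {
    j <- min(i + 3L, n)
    writeLines(paste(sprintf("%.12g", c(s@grid[i], s@values[i:j])),
                     collapse = " "), con)
    i <- j + 1L
  }
  writeLines("##END=", con)
}

.readSpectrumJCAMP <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getField <- function(key) {
    rx <- paste0("^##", key, "=")
    hit <- grep(rx, lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(rx, "", hit[1]))
  }
  xf <- as.numeric(getField("XFACTOR") %||% "1")
  yf <- as.numeric(getField("YFACTOR") %||% "1")
  npt <- as.integer(getField("NPOINTS") %||% NA)
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("not a supported JCAMP-DX file (no XYDATA): ", path)
  if (!grepl("\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines[start[1]]))
    stop("unsupported XYDATA form in ", path,
         " (only (X++(Y..Y)) AFFN is supported)")
  end <- grep("^##END", lines)
  end <- end[end > start[1]][1]
  if (is.na(end)) stop("malformed JCAMP-DX (no ##END): ", path)
  body <- lines[(start[1] + 1L):(end - 1L)]
  x <- numeric(0); y <- numeric(0)
  for (k in seq_along(body)) {
    tok <- suppressWarnings(as.numeric(strsplit(trimws(body[k]), "\\s+")[[1]]))
    if (any(!is.finite(tok)))
      stop(sprintf("malformed JCAMP-DX at data line %d of %s", k, path))
    x <- c(x, tok[1])
    y <- c(y, tok[-1])
  }
  if (!is.na(npt) && length(y) != npt)
    stop(sprintf("JCAMP-DX NPOINTS=%d but %d values read in %s",
                 npt, length(y), path))
  firstx <- as.numeric(getField("FIRSTX") %||% x[1]) * xf
  lastx <- as.numeric(getField("LASTX") %||% x[length(x)]) * xf
  grid <- seq(firstx, lastx, length.out = length(y))
  role <- "absorbance"
  yu <- getField("YUNITS")
  if (!is.null(yu) && grepl("MOLAR ABSORPTIVITY", yu, ignore.case = TRUE))
    role <- "molar_absorptivity"
  Spectrum(grid, y * yf, role = role)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
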