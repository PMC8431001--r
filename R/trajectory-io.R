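## Trajectory accessors and text-format I/O: extended XYZ (box lengths in a
## Lattice= comment) and GRO.

#' Trajectory accessors
#'
#' @param object a [Trajectory-class].
#' @param i frame index.
#' @name Trajectory-accessors
NULL

#' @rdname Trajectory-accessors
#' @export
setMethod("nFrames", "Trajectory", function(object) length(object@coords))

#' @rdname Trajectory-accessors
#' @export
setMethod("nAtoms", "Trajectory", function(object) nrow(object@coords[[1]]))

#' @rdname Trajectory-accessors
#' @export
setMethod("frameCoords", "Trajectory",
          function(object, i) object@coords[[i]])

#' @rdname Trajectory-accessors
#' @export
setMethod("boxLengths", "Trajectory", function(object, i) {
  if (missing(i)) i <- 1L
  object@box[i, ]
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d atoms, box %.2f x %.2f x %.2f A\n",
              nFrames(object), nAtoms(object), object@box[1, 1],
              object@box[1, 2], object@box[1, 3]))
})

#' Write a trajectory as extended XYZ
#'
#' One block per frame: the atom count, a comment line carrying
#' `Lattice="lx 0 0 0 ly 0 0 0 lz" Properties=species:S:1:pos:R:3`, then one
#' `element x y z` line per atom (Angstrom).
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeXYZ <- function(traj, path) {
  stopifnot(methods::is(traj, "Trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nFrames(traj))) {
    x <- traj@coords[[i]]
    L <- traj@box[i, ]
    writeLines(as.character(nrow(x)), con)
    writeLines(sprintf(
      'Lattice="%.12g 0 0 0 %.12g 0 0 0 %.12g" Properties=species:S:1:pos:R:3',
      L[1], L[2], L[3]), con)
    writeLines(sprintf("%s %.12g %.12g %.12g", traj@elements, x[, 1], x[, 2],
                       x[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' @param path input file written in the dialect of [writeXYZ()] (any
#'   extended-XYZ file with a diagonal `Lattice=` entry works).
#' @return A [Trajectory-class].
#' @export
readXYZ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  coords <- list()
  boxes <- NULL
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ at line ", i, ": expected atom count")
    comment <- lines[i + 1L]
    m <- regmatches(comment,
                    regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(m) < 2L)
      stop("XYZ frame at line ", i, " has no Lattice= box entry")
    lat <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
    if (length(lat) == 9L) lat <- lat[c(1, 5, 9)]
    if (length(lat) != 3L || any(!is.finite(lat)))
      stop("unsupported Lattice entry at line ", i + 1L)
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    el <- vapply(tok, `[[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("malformed coordinates in XYZ frame at line ", i)
    coords[[length(coords) + 1L]] <- xyz
    boxes <- rbind(boxes, lat)
    if (is.null(elements)) elements <- el
    i <- i + 2L + n
  }
  rownames(boxes) <- NULL
  Trajectory(coords, boxes, elements)
}

#' Read a GRO trajectory
#'
#' Parses (possibly concatenated multi-frame) GROMACS GRO files with an
#' orthorhombic box line; coordinates are converted from nm to Angstrom.
#' Elements are taken as the first letter of the atom name.
#'
#' @param path input file.
#' @return A [Trajectory-class].
#' @export
readGRO <- function(path) {
  lines <- readLines(path, warn = FALSE)
  coords <- list()
  boxes <- NULL
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop("malformed GRO at line ", i + 1L,
                       ": expected atom count")
    block <- lines[(i + 2L):(i + 1L + n)]
    name <- trimws(substr(block, 11L, 15L))
    xyz <- cbind(as.numeric(substr(block, 21L, 28L)),
                 as.numeric(substr(block, 29L, 36L)),
                 as.numeric(substr(block, 37L, 44L))) * 10
    if (any(!is.finite(xyz)))
      stop("malformed coordinates in GRO frame starting at line ", i)
    boxTok <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])
    if (length(boxTok) < 3L || any(!is.finite(boxTok[1:3])))
      stop("malformed GRO box line at line ", i + 2L + n)
    coords[[length(coords) + 1L]] <- xyz
    boxes <- rbind(boxes, boxTok[1:3] * 10)
    if (is.null(elements)) elements <- substr(name, 1L, 1L)
    i <- i + 3L + n
  }
  rownames(boxes) <- NULL
  Trajectory(coords, boxes, elements)
}
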