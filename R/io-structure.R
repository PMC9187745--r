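## GRO / XYZ readers and writers.  Each "atom" record carries one molecular
## center; GRO velocities are ignored.  No installed R package parses these
## formats, so they are implemented here against the published layouts.

#' Read a structure file into a Frame
#'
#' Reads a GRO or XYZ coordinate file of molecular centers.  GRO follows the
#' GROMACS fixed-width layout (coordinates in nm, 3 decimals); XYZ is the
#' free-format convention with the box carried on the comment line as
#' `box: Lx Ly Lz` (or supplied via `box`).  Coordinates are wrapped into
#' `[0, L)` per axis after reading.
#'
#' @param path file path.
#' @param format `"GRO"` or `"XYZ"`; default guessed from the extension.
#' @param xyzUnit unit of XYZ coordinates (GRO is always nm).
#' @param box optional three box edges (in `xyzUnit` for XYZ), overriding
#'   any box found in the file.
#' @return a [Frame-class].
#' @examples
#' tmp <- tempfile(fileext = ".gro")
#' fr <- makeFrame(matrix(runif(30, 0, 5), ncol = 3), box = c(5, 5, 5))
#' writeStructure(fr, tmp)
#' fr2 <- readStructure(tmp)
#' @export
readStructure <- function(path, format = c("guess", "GRO", "XYZ"),
                          xyzUnit = "nm", box = NULL) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "XYZ" else "GRO"
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "GRO") .readGRO(lines, path, box)
  else .readXYZ(lines, path, xyzUnit, box)
}

.parseError <- function(path, lineno, what) {
  stop(sprintf("parse error in '%s' at line %d: %s", path, lineno, what),
       call. = FALSE)
}

.readGRO <- function(lines, path, box = NULL) {
  if (length(lines) < 3) .parseError(path, length(lines), "truncated GRO file")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n <= 0)
    .parseError(path, 2L, "atom count missing or non-positive")
  if (length(lines) < n + 3)
    .parseError(path, length(lines),
                sprintf("expected %d atom lines plus a box line", n))
  atom <- lines[3:(n + 2)]
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- atom[i]
    if (nchar(ln) < 44)
      .parseError(path, i + 2L, "atom line shorter than the GRO fixed width")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                         substr(ln, 29, 36),
                                         substr(ln, 37, 44))))
    if (any(is.na(xyz)))
      .parseError(path, i + 2L, "unparseable coordinate field")
    coords[i, ] <- xyz
  }
  if (is.null(box)) {
    box <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]),
                                                "\\s+")[[1]]))
    if (length(box) < 3 || any(is.na(box[1:3])))
      .parseError(path, n + 3L, "unparseable box line")
    box <- box[1:3]
  }
  if (any(box <= 0))
    stop("non-positive box edge in '", path, "'", call. = FALSE)
  makeFrame(coords, box)
}

.readXYZ <- function(lines, path, xyzUnit = "nm", box = NULL) {
  if (length(lines) < 2) .parseError(path, length(lines), "truncated XYZ file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n <= 0)
    .parseError(path, 1L, "atom count missing or non-positive")
  if (length(lines) < n + 2)
    .parseError(path, length(lines), sprintf("expected %d atom lines", n))
  if (is.null(box)) {
    m <- regmatches(lines[2], regexec(
      "box:?\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)", lines[2]))[[1]]
    if (length(m) == 4) box <- as.numeric(m[2:4])
    else .parseError(path, 2L,
                     "no 'box: Lx Ly Lz' on the comment line and no box given")
  }
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
    if (length(tok) < 4)
      .parseError(path, i + 2L, "expected 'element x y z'")
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz)))
      .parseError(path, i + 2L, "unparseable coordinate field")
    coords[i, ] <- xyz
  }
  if (any(box <= 0))
    stop("non-positive box edge in '", path, "'", call. = FALSE)
  scl <- toSI(1, xyzUnit) / toSI(1, "nm")   # convert declared unit to nm
  makeFrame(coords * scl, box * scl)
}

#' Write a Frame to a structure file
#'
#' GRO output uses the GROMACS fixed-width columns with 3-decimal positions
#' (which bounds the round-trip precision at 1e-3 nm); XYZ output carries
#' the box on the comment line as `box: Lx Ly Lz` and 6-decimal positions.
#' Empty frames are rejected.
#'
#' @param frame a [Frame-class].
#' @param path output file path.
#' @param format `"GRO"` or `"XYZ"`; default guessed from the extension.
#' @param title title/comment line content.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(frame, path, format = c("guess", "GRO", "XYZ"),
                           title = "cntrates frame") {
  stopifnot(is(frame, "Frame"))
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "XYZ" else "GRO"
  xyz <- positions(frame)
  n <- nrow(xyz)
  if (n == 0) stop("refusing to write an empty frame (zero molecules)")
  box <- boxEdges(frame)
  lines <- if (format == "GRO") {
    c(title, sprintf("%5d", n),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              seq_len(n) %% 100000L, "MOL", "C", seq_len(n) %% 100000L,
              xyz[, 1], xyz[, 2], xyz[, 3]),
      sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  } else {
    c(sprintf("%d", n),
      sprintf("%s box: %.6f %.6f %.6f", title, box[1], box[2], box[3]),
      sprintf("C %.6f %.6f %.6f", xyz[, 1], xyz[, 2], xyz[, 3]))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to '", path, "'", call. = FALSE)
  invisible(path)
}

#' Minimum-image displacement vectors
#'
#' Displacements `b - a` reduced by the minimum-image convention in an
#' orthorhombic periodic box.
#'
#' @param a,b n x 3 coordinate matrices (or length-3 vectors), nm.
#' @param box three box edges, nm.
#' @return n x 3 matrix of minimum-image displacements.
#' @export
minimumImage <- function(a, b, box) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d <- b - a
  sweep(d, 2, box, function(x, L) x - L * round(x / L))
}
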