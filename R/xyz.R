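# Standard XYZ dialect: atom-count line, free-form comment line, then one
# record per atom: element symbol + x y z in Angstrom. Multi-frame files are
# concatenations of such blocks.

# Masses (amu) and single-bond covalent radii (Angstrom, Cordero-type values)
# for the elements this package is likely to see. Connectivity auto-derivation
# and mass-weighting both draw on this table.
element_data <- data.frame(
  symbol = c("H", "He", "B", "C", "N", "O", "F", "Ne", "Na", "Mg",
             "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Br", "I"),
  mass = c(1.008, 4.002602, 10.81, 12.011, 14.007, 15.999, 18.998403,
           20.1797, 22.989769, 24.305, 26.981539, 28.085, 30.973762,
           32.06, 35.45, 39.948, 39.0983, 40.078, 79.904, 126.90447),
  radius = c(0.31, 0.28, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58, 1.66, 1.41,
             1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76, 1.20, 1.39),
  stringsAsFactors = FALSE
)

element_masses <- function(elements) {
  i <- match(elements, element_data$symbol)
  if (anyNA(i))
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "), call. = FALSE)
  element_data$mass[i]
}

element_radii <- function(elements) {
  i <- match(elements, element_data$symbol)
  if (anyNA(i))
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "), call. = FALSE)
  element_data$radius[i]
}

#' Read molecular geometries from an XYZ file
#'
#' Parses the standard XYZ dialect (atom-count line, comment line, one
#' `symbol x y z` record per atom, coordinates in Angstrom). Multi-frame
#' trajectory files are supported; frames are returned in file order.
#'
#' @param path Path to an XYZ file.
#' @return A list of frames; each frame is a list with `elements`
#'   (character vector), `coords` (n x 3 numeric matrix, Angstrom) and
#'   `comment` (the second header line). A single-frame file still returns
#'   a length-1 list.
#' @seealso [write_xyz()]
#' @export
read_xyz <- function(path) {
  if (!file.exists(path))
    stop("XYZ file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("line %d: expected an atom count, got '%s'", i, lines[i]),
           call. = FALSE)
    if (i + 1L + n > length(lines))
      stop(sprintf("line %d: frame declares %d atoms but the file ends early",
                   i, n), call. = FALSE)
    comment <- lines[i + 1L]
    elements <- character(n)
    coords <- matrix(NA_real_, n, 3)
    for (j in seq_len(n)) {
      ln <- i + 1L + j
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4L)
        stop(sprintf("line %d: expected 'symbol x y z', got '%s'",
                     ln, lines[ln]), call. = FALSE)
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz))
        stop(sprintf("line %d: non-numeric coordinate in '%s'",
                     ln, lines[ln]), call. = FALSE)
      elements[j] <- tok[1]
      coords[j, ] <- xyz
    }
    element_masses(elements)  # validates symbols
    frames[[length(frames) + 1L]] <-
      list(elements = elements, coords = coords, comment = comment)
    i <- i + 2L + n
  }
  if (!length(frames))
    stop("no frames found in ", path, call. = FALSE)
  frames
}

#' Write geometries to an XYZ file
#'
#' @param frames A single frame (list with `elements` and `coords`) or a
#'   list of frames as returned by [read_xyz()]; a multi-frame input
#'   produces a multi-frame trajectory file.
#' @param path Output path.
#' @param comments Optional character vector of per-frame comment lines.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, comments = NULL) {
  if (!is.null(frames$elements)) frames <- list(frames)
  out <- character(0)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    cm <- if (!is.null(comments)) comments[min(k, length(comments))]
          else if (!is.null(fr$comment)) fr$comment else ""
    out <- c(out, as.character(nrow(fr$coords)), cm,
             sprintf("%-3s %17.10f %17.10f %17.10f",
                     fr$elements, fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}
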