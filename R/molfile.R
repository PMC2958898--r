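# MDL molfile (V2000) and SD file input/output.
#
# The writer emits a fixed-width V2000 connection table: coordinates in
# Angstroms to 4 decimals (z = 0), wedge codes 1 (inclined/up), 6
# (declined/down) and 4 (unknown), charges as M  CHG lines, isotopes as
# M  ISO lines. An explicit hydrogen count h is stored in the atom-block
# hydrogen-count field as h+1 (0 = automatic), which round-trips through this
# reader and is ignored by most other software. Guide placeholders are
# written with the atom symbol "*"; both "*" and "A" are accepted on input.

.wedge_to_stereo <- function(code, line_no) {
  switch(as.character(code),
    "0" = "none", "1" = "inclined", "6" = "declined", "4" = "unknown",
    stop("unknown bond stereo code ", code, " on line ", line_no)
  )
}

.stereo_to_wedge <- function(stereo) {
  c(none = 0L, inclined = 1L, declined = 6L, unknown = 4L)[[stereo]]
}

.int_field <- function(line, from, to, what, line_no) {
  v <- suppressWarnings(as.integer(trimws(substr(line, from, to))))
  if (is.na(v)) stop("malformed ", what, " on line ", line_no)
  v
}

#' Read an MDL molfile (V2000)
#'
#' @param text A molfile as a single string, a character vector of lines, or
#'   the path to a file.
#' @return A [molecule()]. The z coordinate is ignored.
#' @export
read_molfile <- function(text) {
  lines <- .as_lines(text)
  parse_molfile_lines(lines, offset = 0)
}

.as_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  if (length(text) == 1) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}

parse_molfile_lines <- function(lines, offset = 0) {
  if (length(lines) < 4) stop("molfile truncated: no counts line")
  counts <- lines[4]
  if (nchar(counts) < 6 || !grepl("^[ 0-9]{6}", counts))
    stop("malformed counts line on line ", offset + 4)
  na <- .int_field(counts, 1, 3, "atom count", offset + 4)
  nb <- .int_field(counts, 4, 6, "bond count", offset + 4)
  if (length(lines) < 4 + na + nb) stop("molfile truncated: atom/bond block short")

  m <- molecule()
  for (i in seq_len(na)) {
    ln <- lines[4 + i]
    x <- suppressWarnings(as.numeric(substr(ln, 1, 10)))
    y <- suppressWarnings(as.numeric(substr(ln, 11, 20)))
    if (is.na(x) || is.na(y)) stop("malformed atom coordinates on line ", offset + 4 + i)
    sym <- trimws(substr(ln, 32, 34))
    if (sym == "A") sym <- "*"
    hh <- suppressWarnings(as.integer(trimws(substr(ln, 43, 45))))
    hyd <- if (!is.na(hh) && hh > 0) hh - 1L else NA_integer_
    m <- add_atom(m, sym, x, y, hydrogens = hyd)
  }
  for (i in seq_len(nb)) {
    ln <- lines[4 + na + i]
    from <- .int_field(ln, 1, 3, "bond atom", offset + 4 + na + i)
    to <- .int_field(ln, 4, 6, "bond atom", offset + 4 + na + i)
    ord <- .int_field(ln, 7, 9, "bond order", offset + 4 + na + i)
    wcode <- suppressWarnings(as.integer(trimws(substr(ln, 10, 12))))
    if (is.na(wcode)) wcode <- 0L
    if (!ord %in% 0:4) stop("unsupported bond order ", ord, " on line ", offset + 4 + na + i)
    m <- add_bond(m, from, to, ord, .wedge_to_stereo(wcode, offset + 4 + na + i))
  }
  # property block
  for (ln in lines[-seq_len(4 + na + nb)]) {
    if (startsWith(ln, "M  END")) break
    if (startsWith(ln, "M  CHG") || startsWith(ln, "M  ISO")) {
      kind <- substr(ln, 4, 6)
      nn <- as.integer(trimws(substr(ln, 7, 9)))
      for (k in seq_len(nn)) {
        base <- 10 + (k - 1) * 8
        ai <- as.integer(trimws(substr(ln, base, base + 3)))
        vv <- as.integer(trimws(substr(ln, base + 4, base + 7)))
        if (kind == "CHG") m$atoms$charge[ai] <- vv else m$atoms$isotope[ai] <- vv
      }
    }
    if (startsWith(ln, "M  RAD")) {
      nn <- as.integer(trimws(substr(ln, 7, 9)))
      for (k in seq_len(nn)) {
        base <- 10 + (k - 1) * 8
        ai <- as.integer(trimws(substr(ln, base, base + 3)))
        vv <- as.integer(trimws(substr(ln, base + 4, base + 7)))
        # MDL radical codes: 1 = singlet, 2 = doublet, 3 = triplet
        m$atoms$unpaired[ai] <- c(0L, 1L, 2L)[vv]
      }
    }
  }
  validate_molecule(m)
  m
}

#' Write an MDL molfile (V2000)
#'
#' @param m A [molecule()] with at most 999 atoms and 999 bonds.
#' @param title Optional title for the header block.
#' @return A single string containing the molfile text (inverse of
#'   [read_molfile()] up to float formatting).
#' @export
write_molfile <- function(m, title = "") {
  if (n_atoms(m) > 999 || n_bonds(m) > 999)
    stop("V2000 molfiles support at most 999 atoms and 999 bonds")
  out <- c(title, "  sketchmol", "")
  out <- c(out, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_atoms(m), n_bonds(m)))
  a <- m$atoms
  for (i in seq_len(n_atoms(m))) {
    hh <- if (is.na(a$hydrogens[i])) 0L else a$hydrogens[i] + 1L
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0%3d  0  0  0  0  0  0  0  0",
                          a$x[i], a$y[i], 0, a$element[i], hh))
  }
  b <- m$bonds
  for (i in seq_len(n_bonds(m))) {
    out <- c(out, sprintf("%3d%3d%3d%3d  0  0  0", b$from[i], b$to[i], b$order[i],
                          .stereo_to_wedge(b$stereo[i])))
  }
  chg <- which(m$atoms$charge != 0)
  for (i in chg)
    out <- c(out, sprintf("M  CHG%3d%4d%4d", 1L, i, m$atoms$charge[i]))
  iso <- which(!is.na(m$atoms$isotope))
  for (i in iso)
    out <- c(out, sprintf("M  ISO%3d%4d%4d", 1L, i, m$atoms$isotope[i]))
  rad <- which(m$atoms$unpaired > 0)
  for (i in rad)
    out <- c(out, sprintf("M  RAD%3d%4d%4d", 1L, i,
                          if (m$atoms$unpaired[i] == 1) 2L else 3L))
  out <- c(out, "M  END")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Read an MDL SD file (multi-record)
#'
#' @param text SD file contents as a string, lines, or a file path.
#' @return A list of [molecule()]s, one per `$$$$`-terminated record; a
#'   `name` attribute per element carries the record title line.
#' @export
read_sdf <- function(text) {
  lines <- .as_lines(text)
  # split on $$$$ delimiters
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) ends <- length(lines)
  starts <- c(1, head(ends, -1) + 1)
  mols <- list()
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:min(ends[k], length(lines))]
    rec <- rec[trimws(rec) != "$$$$"]
    if (!any(nzchar(trimws(rec)))) next
    # drop data items (everything from the first "> <...>" line on)
    dstart <- grep("^>", rec)
    mrec <- if (length(dstart)) rec[seq_len(dstart[1] - 1)] else rec
    mol <- parse_molfile_lines(mrec, offset = starts[k] - 1)
    attr(mol, "name") <- trimws(rec[1])
    mols[[length(mols) + 1]] <- mol
  }
  mols
}

#' Write an MDL SD file
#'
#' @param mols A list of [molecule()]s (or a single molecule).
#' @param names Optional record titles.
#' @return A single string: concatenated molfiles, each followed by `$$$$`.
#' @export
write_sdf <- function(mols, names = NULL) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  if (is.null(names)) names <- vapply(mols, function(m) {
    nm <- attr(m, "name", exact = TRUE); if (is.null(nm)) "" else nm
  }, character(1))
  recs <- mapply(function(m, nm) paste0(write_molfile(m, title = nm), "$$$$\n"),
                 mols, names)
  paste(recs, collapse = "")
}
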