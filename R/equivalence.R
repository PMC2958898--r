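#' Sketch equivalence of two structures
#'
#' Two sketches are equivalent when they are the same drawing, not merely the
#' same molecule: atom and bond counts must agree; after translating both so
#' their centres coincide, each atom of `a` must map uniquely to an atom of
#' `b` within 0.2 Angstroms; mapped atoms must agree in element, charge,
#' unpaired electrons, isotope and hydrogen mode; and every bond must have a
#' counterpart with the same order and stereo style. For wedge bonds
#' (inclined/declined) the from/to direction must map forward; for all other
#' bonds the inverse mapping is also permitted. Alternate tautomers and
#' Kekule resonance forms therefore compare as different — deliberately so
#' for sketching, in contrast to canonical identifiers such as unique SMILES
#' or InChI.
#'
#' The positional mapping is greedy nearest-neighbour: candidate pairs are
#' taken in ascending distance order with uniqueness enforced on both sides.
#'
#' @param a,b [molecule()]s.
#' @param tol Mapping tolerance in Angstroms (0.2 by default).
#' @return `TRUE` or `FALSE`.
#' @export
structures_equivalent <- function(a, b, tol = 0.2) {
  if (n_atoms(a) != n_atoms(b) || n_bonds(a) != n_bonds(b)) return(FALSE)
  n <- n_atoms(a)
  if (n == 0) return(TRUE)
  ax <- a$atoms$x - mean(a$atoms$x); ay <- a$atoms$y - mean(a$atoms$y)
  bx <- b$atoms$x - mean(b$atoms$x); by <- b$atoms$y - mean(b$atoms$y)
  # any within-tol bijection forces the sorted coordinate arrays to agree
  # elementwise within tol, so mismatch there is a cheap rejection
  if (max(abs(sort(ax) - sort(bx))) > tol || max(abs(sort(ay) - sort(by))) > tol)
    return(FALSE)
  d <- outer(ax, bx, `-`)^2 + outer(ay, by, `-`)^2
  map <- greedy_assign(sqrt(d), tol = tol)
  if (is.null(map)) return(FALSE)

  fa <- a$atoms; fb <- cols_subset(b$atoms, map)
  same <- fa$element == fb$element & fa$charge == fb$charge &
    fa$unpaired == fb$unpaired &
    (is.na(fa$isotope) == is.na(fb$isotope)) &
    (is.na(fa$isotope) | fa$isotope == fb$isotope) &
    (is.na(fa$hydrogens) == is.na(fb$hydrogens)) &
    (is.na(fa$hydrogens) | fa$hydrogens == fb$hydrogens)
  if (!all(same %in% TRUE)) return(FALSE)

  if (n_bonds(a)) {
    af <- map[a$bonds$from]; at <- map[a$bonds$to]
    bf <- b$bonds$from; bt <- b$bonds$to
    idx <- match(paste(pmin(af, at), pmax(af, at)),
                 paste(pmin(bf, bt), pmax(bf, bt)))
    if (anyNA(idx)) return(FALSE)
    if (!all(b$bonds$order[idx] == a$bonds$order)) return(FALSE)
    if (!all(b$bonds$stereo[idx] == a$bonds$stereo)) return(FALSE)
    wedge <- a$bonds$stereo %in% c("inclined", "declined")
    if (any(wedge & !(bf[idx] == af & bt[idx] == at))) return(FALSE)
  }
  TRUE
}
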