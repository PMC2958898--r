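#' Sketch state: a molecule plus its editing subject
#'
#' A `sketch_state` carries the molecule being drawn together with the
#' annotation each primitive acts on: at any time there may be a current atom
#' or a current bond, but not both, plus a set of selected atoms. The
#' *subject atoms* of a primitive are the selected atoms if any exist,
#' otherwise the current atom, otherwise the two atoms of the current bond,
#' otherwise the empty set — see [subject_atoms()].
#'
#' @param molecule A [molecule()].
#' @param current_atom Atom index, or `NA`.
#' @param current_bond Bond row index, or `NA`. Mutually exclusive with
#'   `current_atom`.
#' @param selection Integer vector of selected atom indices.
#' @return An object of class `sketch_state`.
#' @export
sketch_state <- function(molecule = sketchmol::molecule(), current_atom = NA_integer_,
                         current_bond = NA_integer_, selection = integer()) {
  s <- structure(list(
    molecule = molecule,
    current_atom = as.integer(current_atom),
    current_bond = as.integer(current_bond),
    selection = sort(unique(as.integer(selection)))
  ), class = "sketch_state")
  validate_state(s)
}

validate_state <- function(s) {
  if (!is.na(s$current_atom) && !is.na(s$current_bond))
    stop("a sketch may have a current atom or a current bond, but not both")
  n <- n_atoms(s$molecule)
  if (!is.na(s$current_atom) && (s$current_atom < 1 || s$current_atom > n))
    stop("current atom out of range")
  if (!is.na(s$current_bond) && (s$current_bond < 1 || s$current_bond > n_bonds(s$molecule)))
    stop("current bond out of range")
  if (length(s$selection) && (min(s$selection) < 1 || max(s$selection) > n))
    stop("selection references a missing atom")
  s
}

#' @rdname sketch_state
#' @param s A `sketch_state`.
#' @param atom Atom index.
#' @export
set_current_atom <- function(s, atom) {
  s$current_atom <- as.integer(atom)
  s$current_bond <- NA_integer_
  validate_state(s)
}

#' @rdname sketch_state
#' @param i,j Atom indices of an existing bond.
#' @export
set_current_bond <- function(s, i, j) {
  bi <- bond_between(s$molecule, i, j)
  if (is.na(bi)) stop("atoms ", i, " and ", j, " are not bonded")
  s$current_bond <- bi
  s$current_atom <- NA_integer_
  validate_state(s)
}

#' @rdname sketch_state
#' @param atoms Integer vector of atom indices (empty clears the selection).
#' @export
set_selection <- function(s, atoms) {
  s$selection <- sort(unique(as.integer(atoms)))
  validate_state(s)
}

#' @rdname sketch_state
#' @export
clear_subject <- function(s) {
  s$current_atom <- NA_integer_
  s$current_bond <- NA_integer_
  s$selection <- integer()
  s
}

#' Resolve the subject atoms of a sketch state
#'
#' Returns all selected atoms if there are any; otherwise the current atom if
#' there is one; otherwise the two atoms of the current bond; otherwise the
#' empty set. Selected atoms are returned in ascending index order; for a
#' current bond the order is `[from, to]`.
#'
#' @param s A [sketch_state()].
#' @return Integer vector of atom indices (possibly empty).
#' @export
subject_atoms <- function(s) {
  if (length(s$selection)) return(s$selection)
  if (!is.na(s$current_atom)) return(s$current_atom)
  if (!is.na(s$current_bond)) {
    b <- s$molecule$bonds
    return(c(b$from[s$current_bond], b$to[s$current_bond]))
  }
  integer()
}

# Re-point current/selection through an old->new atom index map (NA = gone).
remap_state <- function(s, map) {
  if (!is.na(s$current_atom)) {
    s$current_atom <- map[s$current_atom]
    if (is.na(s$current_atom)) s$current_atom <- NA_integer_
  }
  s$selection <- sort(s$selection[!is.na(map[s$selection])])
  if (length(s$selection)) s$selection <- map[s$selection]
  s
}

#' @export
print.sketch_state <- function(x, ...) {
  print(x$molecule)
  if (!is.na(x$current_atom)) cat("  current atom:", x$current_atom, "\n")
  if (!is.na(x$current_bond)) {
    b <- x$molecule$bonds
    cat(sprintf("  current bond: %d-%d\n", b$from[x$current_bond], b$to[x$current_bond]))
  }
  if (length(x$selection)) cat("  selection:", paste(x$selection, collapse = " "), "\n")
  invisible(x)
}
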