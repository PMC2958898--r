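#' Molecular connection tables with 2D coordinates
#'
#' A `molecule` is the sketch's connection table: an ordered atom list and an
#' ordered bond list. Atoms carry an element symbol (a periodic element, an
#' abbreviation, or the `"*"` guide placeholder), an ionic charge, an unpaired
#' electron (radical) count, an isotope (mass number, or `NA` for natural
#' abundance), a hydrogen count (`NA` for automatic) and x/y coordinates in
#' Angstroms. Bonds are ordered pairs of atom indices — the order is
#' significant for wedge bonds, whose narrow end sits at `from` — with an
#' order in 0:4 and a stereo style in `none`, `inclined` (solid wedge),
#' `declined` (hashed wedge) or `unknown` (wavy).
#'
#' Atom identifiers are stable 1-based row indices into the atom table;
#' deleting atoms renumbers the survivors.
#'
#' @param elements Character vector of atom symbols.
#' @param x,y Numeric coordinate vectors, recycled to the number of atoms.
#' @return An object of class `molecule`.
#' @examples
#' m <- molecule(c("C", "O"), x = c(0, 1.5), y = 0)
#' m <- add_bond(m, 1, 2, order = 2)
#' n_atoms(m)
#' @export
molecule <- function(elements = character(), x = numeric(), y = numeric()) {
  n <- length(elements)
  # atoms and bonds are stored as plain column vectors (not data frames):
  # the grafting pipeline builds thousands of candidate structures and the
  # light container keeps that cheap
  structure(list(
    atoms = list(
      element   = as.character(elements),
      charge    = rep(0L, n),
      unpaired  = rep(0L, n),
      isotope   = rep(NA_integer_, n),
      hydrogens = rep(NA_integer_, n),
      x = rep_len(as.numeric(x), n),
      y = rep_len(as.numeric(y), n)
    ),
    bonds = list(
      from = integer(), to = integer(), order = integer(),
      stereo = character()
    )
  ), class = "molecule")
}

# column-set helpers: subset all columns by index, or concatenate two sets
cols_subset <- function(l, idx) lapply(l, `[`, idx)
cols_bind <- function(a, b) Map(c, a, b)

BOND_STEREO <- c("none", "inclined", "declined", "unknown")

#' @rdname molecule
#' @param m A `molecule`.
#' @export
n_atoms <- function(m) length(m$atoms$element)

#' @rdname molecule
#' @export
n_bonds <- function(m) length(m$bonds$from)

#' Add an atom to a molecule
#'
#' @param m A `molecule`.
#' @param element Atom symbol.
#' @param x,y Coordinates in Angstroms.
#' @param charge Integer ionic charge.
#' @param unpaired Unpaired electron count (>= 0).
#' @param isotope Mass number, or `NA` for natural abundance.
#' @param hydrogens Explicit hydrogen count (>= 0), or `NA` for automatic.
#' @return The molecule with one more atom (the new atom is the last index).
#' @export
add_atom <- function(m, element, x = 0, y = 0, charge = 0L, unpaired = 0L,
                     isotope = NA_integer_, hydrogens = NA_integer_) {
  stopifnot(is.character(element), nzchar(element), unpaired >= 0)
  if (!is.na(hydrogens) && hydrogens < 0) stop("explicit hydrogen count must be >= 0")
  m$atoms <- cols_bind(m$atoms, list(
    element = element, charge = as.integer(charge), unpaired = as.integer(unpaired),
    isotope = as.integer(isotope), hydrogens = as.integer(hydrogens),
    x = as.numeric(x), y = as.numeric(y)
  ))
  m
}

#' Add a bond to a molecule
#'
#' @param m A `molecule`.
#' @param from,to Atom indices; `from` is the narrow end of a wedge.
#' @param order Bond order, one of 0:4.
#' @param stereo One of `"none"`, `"inclined"`, `"declined"`, `"unknown"`.
#' @return The molecule with the bond appended.
#' @export
add_bond <- function(m, from, to, order = 1L, stereo = "none") {
  from <- as.integer(from); to <- as.integer(to)
  if (from == to) stop("self-bonds are not allowed")
  if (from < 1 || to < 1 || from > n_atoms(m) || to > n_atoms(m))
    stop("bond endpoint references a missing atom")
  if (!order %in% 0:4) stop("bond order must be one of 0, 1, 2, 3, 4")
  if (!stereo %in% BOND_STEREO)
    stop("stereo must be one of ", paste(BOND_STEREO, collapse = ", "))
  if (!is.na(bond_between(m, from, to))) stop("duplicate bond")
  m$bonds <- cols_bind(m$bonds, list(
    from = from, to = to, order = as.integer(order), stereo = stereo
  ))
  m
}

#' Find the bond between two atoms
#'
#' @param m A `molecule`.
#' @param i,j Atom indices (direction is ignored).
#' @return The bond row index, or `NA` if the atoms are not bonded.
#' @export
bond_between <- function(m, i, j) {
  b <- m$bonds
  hit <- which((b$from == i & b$to == j) | (b$from == j & b$to == i))
  if (length(hit)) hit[1] else NA_integer_
}

#' Neighbouring atom indices
#'
#' @param m A `molecule`.
#' @param i Atom index.
#' @return Integer vector of atoms bonded to `i`, ascending.
#' @export
neighbours <- function(m, i) {
  b <- m$bonds
  sort(unique(c(b$to[b$from == i], b$from[b$to == i])))
}

# Bond row indices incident to atom i.
incident_bonds <- function(m, i) which(m$bonds$from == i | m$bonds$to == i)

#' Remove atoms (and their incident bonds)
#'
#' Surviving atoms are renumbered to consecutive indices; the attribute
#' `atom_map` on the result maps old indices to new (`NA` for deleted).
#'
#' @param m A `molecule`.
#' @param ids Atom indices to delete.
#' @return The reduced molecule.
#' @export
remove_atoms <- function(m, ids) {
  ids <- unique(as.integer(ids))
  keep <- setdiff(seq_len(n_atoms(m)), ids)
  map <- rep(NA_integer_, n_atoms(m))
  map[keep] <- seq_along(keep)
  m$atoms <- cols_subset(m$atoms, keep)
  drop <- m$bonds$from %in% ids | m$bonds$to %in% ids
  b <- cols_subset(m$bonds, !drop)
  b$from <- map[b$from]
  b$to <- map[b$to]
  m$bonds <- b
  attr(m, "atom_map") <- map
  m
}

#' Remove bonds by row index
#'
#' @param m A `molecule`.
#' @param idx Bond row indices to delete. Atoms are untouched.
#' @return The reduced molecule.
#' @export
remove_bonds <- function(m, idx) {
  m$bonds <- cols_subset(m$bonds, setdiff(seq_len(n_bonds(m)), as.integer(idx)))
  m
}

# igraph view of the connection table (atoms even if isolated).
mol_graph <- function(m) {
  igraph::graph_from_data_frame(
    data.frame(from = m$bonds$from, to = m$bonds$to),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(m)))
  )
}

# Logical per bond: TRUE when the bond lies in a ring (i.e. is not a bridge).
ring_bond_flags <- function(m) {
  if (n_bonds(m) == 0) return(logical(0))
  g <- mol_graph(m)
  flags <- rep(TRUE, n_bonds(m))
  flags[as.integer(igraph::bridges(g))] <- FALSE
  flags
}

# Atoms in the connected component containing atom i.
component_atoms <- function(m, i) {
  comp <- igraph::components(mol_graph(m))$membership
  which(comp == comp[i])
}

# Atoms on the `nb` side after conceptually deleting the bond centre--nb.
# For an acyclic bond this is the rigid branch hanging off `nb`.
branch_atoms <- function(m, centre, nb) {
  bi <- bond_between(m, centre, nb)
  g <- mol_graph(m)
  if (!is.na(bi)) g <- igraph::delete_edges(g, bi)
  comp <- igraph::components(g)$membership
  which(comp == comp[nb])
}

# Euclidean distance between atoms i and j.
atom_dist <- function(m, i, j) {
  sqrt((m$atoms$x[i] - m$atoms$x[j])^2 + (m$atoms$y[i] - m$atoms$y[j])^2)
}

# Rotate atoms `ids` about (cx, cy) by `deg` counter-clockwise.
rotate_coords <- function(m, ids, cx, cy, deg) {
  th <- deg2rad(deg)
  dx <- m$atoms$x[ids] - cx
  dy <- m$atoms$y[ids] - cy
  m$atoms$x[ids] <- cx + dx * cos(th) - dy * sin(th)
  m$atoms$y[ids] <- cy + dx * sin(th) + dy * cos(th)
  m
}

#' Validate a molecule's structural invariants
#'
#' Checks that bond endpoints exist, no bond is a self-bond, no atom pair is
#' bonded twice, and atom property invariants hold.
#'
#' @param m A `molecule`.
#' @return `m`, invisibly; errors describe the first violated invariant.
#' @export
validate_molecule <- function(m) {
  a <- m$atoms; b <- m$bonds
  if (any(!nzchar(a$element))) stop("empty element symbol")
  if (any(a$unpaired < 0)) stop("negative unpaired electron count")
  if (any(a$hydrogens < 0, na.rm = TRUE)) stop("negative explicit hydrogen count")
  if (n_bonds(m)) {
    if (any(b$from == b$to)) stop("self-bond present")
    if (any(b$from < 1 | b$to < 1 | b$from > n_atoms(m) | b$to > n_atoms(m)))
      stop("bond endpoint references a missing atom")
    key <- paste(pmin(b$from, b$to), pmax(b$from, b$to))
    if (anyDuplicated(key)) stop("duplicate bond present")
    if (!all(b$order %in% 0:4)) stop("unsupported bond order")
    if (!all(b$stereo %in% BOND_STEREO)) stop("unsupported stereo style")
  }
  invisible(m)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms, %d bonds\n", n_atoms(x), n_bonds(x)))
  if (n_atoms(x)) {
    syms <- table(x$atoms$element)
    cat("  atoms:", paste(sprintf("%s%d", names(syms), syms), collapse = " "), "\n")
  }
  invisible(x)
}
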