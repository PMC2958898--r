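# Subject-driven editing primitives: atom property edits, connection,
# deletion, merging and movement. Every primitive takes and returns a
# sketch_state; the atoms acted on are the resolved subject atoms.

DEFAULT_BOND_LENGTH <- 1.5   # Angstroms; applies regardless of atom/bond type
OVERLAP_THRESHOLD <- 0.2     # closer than this and two atoms "overlap"
MERGE_TOLERANCE <- 0.5       # Merge Atoms: significantly under a bond length
GROW_FACTOR <- 1.25
SHRINK_FACTOR <- 0.8
NUDGE_SMALL <- 0.1
NUDGE_LARGE <- 0.5

#' Add a free-standing atom
#'
#' The new atom gets default properties and no bonds, placed along the top
#' and to the right of the existing atoms (at the origin on an empty canvas),
#' and becomes the current atom.
#'
#' @param s A [sketch_state()].
#' @param element Atom symbol for the new atom.
#' @return The updated state.
#' @export
add_atom_primitive <- function(s, element) {
  m <- s$molecule
  if (n_atoms(m) == 0) {
    m <- add_atom(m, element, 0, 0)
  } else {
    m <- add_atom(m, element, max(m$atoms$x) + DEFAULT_BOND_LENGTH, max(m$atoms$y))
  }
  s$molecule <- m
  set_current_atom(s, n_atoms(m))
}

#' Set an atom property on the subject atoms
#'
#' Applies the value to every subject atom. Setting the element with an empty
#' subject maps to the corresponding Add Atom primitive.
#'
#' @param s A [sketch_state()].
#' @param property One of `element`, `charge`, `unpaired`, `hydrogens`,
#'   `isotope`.
#' @param value The new value; `NA` restores the automatic/natural sentinel
#'   for `hydrogens`/`isotope`.
#' @return The updated state.
#' @export
set_atom_property <- function(s, property, value) {
  property <- match.arg(property, c("element", "charge", "unpaired", "hydrogens", "isotope"))
  subj <- subject_atoms(s)
  if (!length(subj)) {
    if (property == "element") return(add_atom_primitive(s, value))
    return(s)
  }
  if (property %in% c("unpaired", "hydrogens") && !is.na(value) && value < 0)
    stop(property, " must be >= 0")
  if (property == "element") {
    s$molecule$atoms$element[subj] <- as.character(value)
  } else {
    s$molecule$atoms[[property]][subj] <- as.integer(value)
  }
  s
}

# All intra-subject bond row indices.
intra_subject_bonds <- function(m, subj) {
  which(m$bonds$from %in% subj & m$bonds$to %in% subj)
}

#' Set the order of the subject bonds
#'
#' With a single-atom subject this maps to [new_bond_with_order()]. With two
#' unbonded subject atoms a new bond of the requested order is created
#' between them. Otherwise all bonds between subject atoms are set to the
#' order, and any previous stereo style on them is reset.
#'
#' @param s A [sketch_state()].
#' @param order Bond order in 0:4.
#' @return The updated state.
#' @export
set_bond_order <- function(s, order) {
  subj <- subject_atoms(s)
  if (length(subj) == 1) return(new_bond_with_order(s, order))
  if (length(subj) == 2 && is.na(bond_between(s$molecule, subj[1], subj[2]))) {
    s$molecule <- add_bond(s$molecule, subj[1], subj[2], order)
    return(s)
  }
  idx <- intra_subject_bonds(s$molecule, subj)
  s$molecule$bonds$order[idx] <- as.integer(order)
  s$molecule$bonds$stereo[idx] <- "none"
  s
}

#' Set the stereo style of the subject bonds
#'
#' With a single-atom subject this maps to [new_bond_with_style()]. With two
#' unbonded subject atoms a new order-1 bond with the style is created (wedge
#' direction follows the atom order). Otherwise intra-subject bonds get the
#' style; bonds already of that style have their from/to reversed, inverting
#' the meaning of the wedge.
#'
#' @param s A [sketch_state()].
#' @param style One of `inclined`, `declined`, `unknown`.
#' @return The updated state.
#' @export
set_stereo_style <- function(s, style) {
  style <- match.arg(style, c("inclined", "declined", "unknown"))
  subj <- subject_atoms(s)
  if (length(subj) == 1) return(new_bond_with_style(s, style))
  if (length(subj) == 2 && is.na(bond_between(s$molecule, subj[1], subj[2]))) {
    s$molecule <- add_bond(s$molecule, subj[1], subj[2], 1L, style)
    return(s)
  }
  idx <- intra_subject_bonds(s$molecule, subj)
  for (i in idx) {
    if (s$molecule$bonds$stereo[i] == style && style %in% c("inclined", "declined")) {
      tmp <- s$molecule$bonds$from[i]
      s$molecule$bonds$from[i] <- s$molecule$bonds$to[i]
      s$molecule$bonds$to[i] <- tmp
    } else {
      s$molecule$bonds$stereo[i] <- style
    }
  }
  s
}

#' Connect subject atoms
#'
#' Every unbonded subject pair whose distance is approximately the default
#' bond distance (within 0.3 Angstroms of 1.5) receives a single bond; when
#' no pair is that close, only the closest unbonded pair is connected.
#'
#' @param s A [sketch_state()].
#' @return The updated state (a warning and no change when fewer than two
#'   subject atoms or no unbonded pair exists).
#' @export
connect_atoms <- function(s) {
  subj <- subject_atoms(s)
  if (length(subj) < 2) {
    warning("connect: fewer than two subject atoms")
    return(s)
  }
  pairs <- t(utils::combn(subj, 2))
  unbonded <- is.na(mapply(function(i, j) bond_between(s$molecule, i, j),
                           pairs[, 1], pairs[, 2]))
  pairs <- pairs[unbonded, , drop = FALSE]
  if (!nrow(pairs)) {
    warning("connect: all subject pairs already bonded")
    return(s)
  }
  d <- mapply(function(i, j) atom_dist(s$molecule, i, j), pairs[, 1], pairs[, 2])
  near <- abs(d - DEFAULT_BOND_LENGTH) <= 0.3
  take <- if (any(near)) which(near) else which.min(d)
  for (k in take) s$molecule <- add_bond(s$molecule, pairs[k, 1], pairs[k, 2], 1L)
  s
}

#' Disconnect subject atoms
#'
#' Deletes every bond whose two atoms are both part of the subject; atoms are
#' not otherwise modified.
#'
#' @param s A [sketch_state()].
#' @return The updated state.
#' @export
disconnect_atoms <- function(s) {
  subj <- subject_atoms(s)
  idx <- intra_subject_bonds(s$molecule, subj)
  if (length(idx)) {
    s$molecule <- remove_bonds(s$molecule, idx)
    s$current_bond <- NA_integer_  # bond rows were renumbered
  }
  s
}

#' Delete atoms, bonds, or everything
#'
#' `atoms` removes the subject atoms and any bonds connected to them; `bonds`
#' removes only intra-subject bonds, leaving atoms untouched; `all` empties
#' the molecule.
#'
#' @param s A [sketch_state()].
#' @param mode One of `atoms`, `bonds`, `all`.
#' @return The updated state.
#' @export
delete_subject <- function(s, mode = c("atoms", "bonds", "all")) {
  mode <- match.arg(mode)
  if (mode == "all") {
    s$molecule <- molecule()
    return(clear_subject(s))
  }
  if (mode == "bonds") return(disconnect_atoms(s))
  subj <- subject_atoms(s)
  s$molecule <- remove_atoms(s$molecule, subj)
  map <- attr(s$molecule, "atom_map")
  s$current_bond <- NA_integer_
  remap_state(s, map)
}

#' Merge nearby subject atoms
#'
#' Each subject atom is examined for other atoms within the merge tolerance
#' (0.5 Angstroms, a third of the default bond distance).
#' Of each such cluster one atom is retained by the exoticness rules
#' (see [merge_overlapping()]) and moved to the average position of the
#' cluster.
#'
#' @param s A [sketch_state()].
#' @param tolerance Merge distance in Angstroms.
#' @return The updated state.
#' @export
merge_atoms <- function(s, tolerance = MERGE_TOLERANCE) {
  subj <- subject_atoms(s)
  if (!length(subj)) stop("merge: empty subject")
  m <- s$molecule
  pending <- subj
  changed <- FALSE
  while (length(pending)) {
    a <- pending[1]; pending <- pending[-1]
    if (is.na(a)) next
    d <- sqrt((m$atoms$x - m$atoms$x[a])^2 + (m$atoms$y - m$atoms$y[a])^2)
    cluster <- which(d <= tolerance)
    if (length(cluster) < 2) next
    cx <- mean(m$atoms$x[cluster]); cy <- mean(m$atoms$y[cluster])
    # retain the most exotic of the cluster (first on a draw), fold the rest in
    repeat {
      exo <- atom_exoticness(m, cluster)
      keep <- cluster[which.max(exo)]
      rest <- setdiff(cluster, keep)
      if (!length(rest)) break
      m <- merge_pair(m, keep, rest[1])
      map <- attr(m, "atom_map")
      map[rest[1]] <- map[keep]
      cluster <- sort(unique(map[cluster]))
      pending <- map[pending]
      changed <- TRUE
    }
    m$atoms$x[cluster] <- cx; m$atoms$y[cluster] <- cy
  }
  s$molecule <- m
  if (changed) {
    s$current_atom <- NA_integer_
    s$current_bond <- NA_integer_
    s$selection <- integer()
  }
  s
}

# Centre about which scale/flip/rotate operate: current atom or bond centre
# when present, else the centroid of the selected atoms.
subject_centre <- function(s, fallback_atoms) {
  m <- s$molecule
  if (!is.na(s$current_atom))
    return(c(m$atoms$x[s$current_atom], m$atoms$y[s$current_atom]))
  if (!is.na(s$current_bond)) {
    ends <- c(m$bonds$from[s$current_bond], m$bonds$to[s$current_bond])
    return(c(mean(m$atoms$x[ends]), mean(m$atoms$y[ends])))
  }
  c(mean(m$atoms$x[fallback_atoms]), mean(m$atoms$y[fallback_atoms]))
}

#' Move the subject atoms
#'
#' Twelve combinations: four directions by three extents. The nudges offset
#' the subject by 0.1 or 0.5 Angstroms; `furthest` computes the offset that
#' places every subject atom 1 Angstrom beyond all other atoms in that
#' direction (no other atoms: no movement).
#'
#' @param s A [sketch_state()].
#' @param direction One of `left`, `right`, `up`, `down`.
#' @param extent One of `small_nudge`, `large_nudge`, `furthest`.
#' @return The updated state.
#' @export
move_atoms <- function(s, direction = c("left", "right", "up", "down"),
                       extent = c("small_nudge", "large_nudge", "furthest")) {
  direction <- match.arg(direction)
  extent <- match.arg(extent)
  subj <- subject_atoms(s)
  if (!length(subj)) stop("move: empty subject")
  m <- s$molecule
  axis <- if (direction %in% c("left", "right")) "x" else "y"
  sign <- if (direction %in% c("right", "up")) 1 else -1
  if (extent == "furthest") {
    others <- setdiff(seq_len(n_atoms(m)), subj)
    if (!length(others)) return(s)
    off <- if (sign > 0) {
      (max(m$atoms[[axis]][others]) + 1) - min(m$atoms[[axis]][subj])
    } else {
      (min(m$atoms[[axis]][others]) - 1) - max(m$atoms[[axis]][subj])
    }
  } else {
    off <- sign * if (extent == "small_nudge") NUDGE_SMALL else NUDGE_LARGE
  }
  m$atoms[[axis]][subj] <- m$atoms[[axis]][subj] + off
  s$molecule <- m
  s
}

#' Scale the subject atoms about their centre
#'
#' Grow and shrink scale distances from the centre by 1.25 and 0.8. The
#' centre is the centroid of the selected atoms unless there is also a
#' current atom or bond, whose central position is then used. With no
#' selection but a current bond, maps to [scale_bond()].
#'
#' @param s A [sketch_state()].
#' @param mode `grow` or `shrink`.
#' @return The updated state.
#' @export
scale_atoms <- function(s, mode = c("grow", "shrink")) {
  mode <- match.arg(mode)
  f <- if (mode == "grow") GROW_FACTOR else SHRINK_FACTOR
  if (!length(s$selection) && !is.na(s$current_bond)) return(scale_bond(s, mode))
  subj <- subject_atoms(s)
  if (!length(subj)) stop("scale: empty subject")
  ctr <- subject_centre(s, subj)
  m <- s$molecule
  m$atoms$x[subj] <- ctr[1] + (m$atoms$x[subj] - ctr[1]) * f
  m$atoms$y[subj] <- ctr[2] + (m$atoms$y[subj] - ctr[2]) * f
  s$molecule <- m
  s
}

#' Scale the subject bond
#'
#' The bond length is scaled by 1.25 (grow) or 0.8 (shrink). For an acyclic
#' bond the side with fewer atoms moves (weights 1/0), the whole branch
#' translating rigidly along the bond axis; equal sides move half each. For
#' a ring bond only the two bonded atoms move apart, half each.
#'
#' @param s A [sketch_state()].
#' @param mode `grow` or `shrink`.
#' @return The updated state.
#' @export
scale_bond <- function(s, mode = c("grow", "shrink")) {
  mode <- match.arg(mode)
  f <- if (mode == "grow") GROW_FACTOR else SHRINK_FACTOR
  subj <- subject_atoms(s)
  if (length(subj) != 2 || is.na(bond_between(s$molecule, subj[1], subj[2])))
    stop("scale bond: subject must be two bonded atoms")
  m <- s$molecule
  i <- subj[1]; j <- subj[2]
  bi <- bond_between(m, i, j)
  cyclic <- ring_bond_flags(m)[bi]
  len <- atom_dist(m, i, j)
  stretch <- len * (f - 1)  # signed change in length
  ux <- (m$atoms$x[j] - m$atoms$x[i]) / len
  uy <- (m$atoms$y[j] - m$atoms$y[i]) / len
  if (cyclic) {
    wi <- wj <- 0.5
    side_i <- i; side_j <- j
  } else {
    side_i <- branch_atoms(m, j, i)
    side_j <- branch_atoms(m, i, j)
    if (length(side_i) < length(side_j)) { wi <- 1; wj <- 0 }
    else if (length(side_j) < length(side_i)) { wi <- 0; wj <- 1 }
    else { wi <- wj <- 0.5 }
  }
  m$atoms$x[side_i] <- m$atoms$x[side_i] - ux * stretch * wi
  m$atoms$y[side_i] <- m$atoms$y[side_i] - uy * stretch * wi
  m$atoms$x[side_j] <- m$atoms$x[side_j] + ux * stretch * wj
  m$atoms$y[side_j] <- m$atoms$y[side_j] + uy * stretch * wj
  s$molecule <- m
  s
}

#' Flip atoms about a horizontal or vertical axis
#'
#' Selected atoms reflect about the axis through the subject centre. When the
#' subject is only a current atom or bond, the whole connected component
#' flips; when the subject is empty, all atoms flip. Wedge directions are
#' not exchanged.
#'
#' @param s A [sketch_state()].
#' @param axis `horizontal` (x changes) or `vertical` (y changes).
#' @return The updated state.
#' @export
flip_atoms <- function(s, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  m <- s$molecule
  if (length(s$selection)) {
    subj <- s$selection
  } else if (!is.na(s$current_atom)) {
    subj <- component_atoms(m, s$current_atom)
  } else if (!is.na(s$current_bond)) {
    subj <- component_atoms(m, m$bonds$from[s$current_bond])
  } else {
    subj <- seq_len(n_atoms(m))
  }
  if (!length(subj)) return(s)
  ctr <- subject_centre(s, subj)
  if (axis == "horizontal") {
    m$atoms$x[subj] <- 2 * ctr[1] - m$atoms$x[subj]
  } else {
    m$atoms$y[subj] <- 2 * ctr[2] - m$atoms$y[subj]
  }
  s$molecule <- m
  s
}

#' Rotate the subject atoms by a fixed increment
#'
#' Rotates about the subject centre (positive = counter-clockwise). Special
#' case: with no selection and a current bond having exactly one terminal
#' end, the terminal atom orbits the non-terminal end.
#'
#' @param s A [sketch_state()].
#' @param increment Rotation in degrees, typically one of ±1, ±5, ±15, ±30.
#' @return The updated state.
#' @export
rotate_atoms <- function(s, increment) {
  m <- s$molecule
  if (!length(s$selection) && !is.na(s$current_bond)) {
    bf <- m$bonds$from[s$current_bond]; bt <- m$bonds$to[s$current_bond]
    deg_f <- length(neighbours(m, bf))
    deg_t <- length(neighbours(m, bt))
    if (xor(deg_f == 1, deg_t == 1)) {
      term <- if (deg_f == 1) bf else bt
      pivot <- if (deg_f == 1) bt else bf
      s$molecule <- rotate_coords(m, term, m$atoms$x[pivot], m$atoms$y[pivot], increment)
      return(s)
    }
  }
  subj <- subject_atoms(s)
  if (!length(subj)) stop("rotate: empty subject")
  ctr <- subject_centre(s, subj)
  s$molecule <- rotate_coords(m, subj, ctr[1], ctr[2], increment)
  s
}
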