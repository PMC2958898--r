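# Geometry-aware structure growth. New bonds extend to the default bond
# length (1.5 Angstroms); among the inferred candidate angles the point of
# lowest congestion wins, ties broken by the smallest candidate angle.

# Pick the least congested candidate angle around `atom`; returns the angle.
least_congested_angle <- function(m, atom, angles) {
  px <- m$atoms$x[atom] + DEFAULT_BOND_LENGTH * cos(deg2rad(angles))
  py <- m$atoms$y[atom] + DEFAULT_BOND_LENGTH * sin(deg2rad(angles))
  cong <- vapply(seq_along(angles), function(k) point_congestion(m, px[k], py[k]),
                 numeric(1))
  best <- which(cong <= min(cong) + 1e-12)
  angles[best[which.min(angles[best])]]
}

# Shared worker: attach a new neutral carbon to `atom` at the least congested
# inferred angle (molecule-level).
attach_new_atom_mol <- function(m, atom, order, stereo = "none") {
  angles <- propose_new_bond_angles(m, atom, order)
  a <- least_congested_angle(m, atom, angles)
  m <- add_atom(m, "C",
                m$atoms$x[atom] + DEFAULT_BOND_LENGTH * cos(deg2rad(a)),
                m$atoms$y[atom] + DEFAULT_BOND_LENGTH * sin(deg2rad(a)))
  add_bond(m, atom, n_atoms(m), order, stereo)
}

attach_new_atom <- function(s, atom, order, stereo = "none") {
  s$molecule <- attach_new_atom_mol(s$molecule, atom, order, stereo)
  set_current_atom(s, n_atoms(s$molecule))
}

#' Create a new bonded atom with a given bond order
#'
#' Candidate angles come from [propose_new_bond_angles()]; each is extended
#' to the default bond length and the point with the lowest congestion
#' receives a new neutral carbon atom, bonded to the subject atom with the
#' requested order. The new atom becomes current. With a multi-atom
#' selection each selected atom receives its own new bond and the selection
#' is retained.
#'
#' @param s A [sketch_state()] with a non-empty subject.
#' @param order Bond order in 0:4.
#' @return The updated state (unchanged, with a warning, on an empty subject).
#' @export
new_bond_with_order <- function(s, order = 1L) {
  subj <- subject_atoms(s)
  if (length(subj) == 0) {
    warning("new bond: empty subject")
    return(s)
  }
  if (length(subj) > 1) {
    # one new bond per selected atom; the selection is retained so the
    # primitive can be issued repeatedly
    for (a in subj) s$molecule <- attach_new_atom_mol(s$molecule, a, as.integer(order))
    return(s)
  }
  attach_new_atom(s, subj, as.integer(order))
}

#' Create a new bonded atom with a stereo style
#'
#' Positioning as [new_bond_with_order()] with order 1; the new bond carries
#' the style, with the wedge emanating from the subject atom (`from` = the
#' subject).
#'
#' @param s A [sketch_state()] whose subject resolves to exactly one atom.
#' @param style One of `inclined`, `declined`, `unknown`.
#' @return The updated state.
#' @export
new_bond_with_style <- function(s, style) {
  style <- match.arg(style, c("inclined", "declined", "unknown"))
  subj <- subject_atoms(s)
  if (length(subj) == 0) {
    warning("new bond: empty subject")
    return(s)
  }
  if (length(subj) > 1) stop("new bond: subject must be a single atom")
  attach_new_atom(s, subj, 1L, style)
}

#' Create a new bonded atom using an explicit geometry
#'
#' If the current geometry about the subject atom matches the requested
#' template with at least one vacancy, all implied vacancy positions are
#' scored by congestion and the least congested receives a new carbon with a
#' single bond. Otherwise the operation maps to [set_geometry()].
#'
#' @param s A [sketch_state()] whose subject resolves to exactly one atom.
#' @param template Geometry template name (see [geometry_template()]).
#' @return The updated state.
#' @export
new_bond_with_geometry <- function(s, template) {
  subj <- subject_atoms(s)
  if (length(subj) != 1) stop("new bond with geometry: subject must be a single atom")
  m <- s$molecule
  v <- match_template(bond_angles_at(m, subj), template)
  if (is.null(v) || !length(v)) return(set_geometry(s, template))
  a <- least_congested_angle(m, subj, v)
  m <- add_atom(m, "C",
                m$atoms$x[subj] + DEFAULT_BOND_LENGTH * cos(deg2rad(a)),
                m$atoms$y[subj] + DEFAULT_BOND_LENGTH * sin(deg2rad(a)))
  m <- add_bond(m, subj, n_atoms(m), 1L)
  s$molecule <- m
  set_current_atom(s, n_atoms(m))
}

#' Refit the subject atoms to a geometry template
#'
#' Applies [refit_to_geometry()] to each subject atom: atoms already
#' matching the template are left unchanged; otherwise their neighbours are
#' rotated (whole acyclic branches moving rigidly) into the template's slots
#' with the smallest overall angular displacement. Atoms where every
#' assignment would move a ring bond are skipped; if that happens for all
#' subject atoms the state is returned unchanged with a warning.
#'
#' @param s A [sketch_state()].
#' @param template Geometry template name.
#' @return The updated state.
#' @export
set_geometry <- function(s, template) {
  subj <- subject_atoms(s)
  if (!length(subj)) stop("set geometry: empty subject")
  any_ok <- FALSE
  for (a in subj) {
    if (!length(neighbours(s$molecule, a))) next
    res <- refit_to_geometry(s$molecule, a, template)
    if (!is.null(res)) {
      s$molecule <- res
      any_ok <- TRUE
    }
  }
  if (!any_ok) warning("set geometry: no subject atom could be refitted")
  s
}

#' Rotate a terminal bond to the next position in its geometry
#'
#' The subject must be a bond with exactly one terminal end. The geometry of
#' the non-terminal end is estimated as if the bond were not present; the
#' non-degenerate vacancies that differ from the original bearing are the
#' viable positions, and the bond rotates (its length preserved) to the one
#' with the smallest anti-clockwise increment — so repeated invocation
#' cycles through every available position.
#'
#' @param s A [sketch_state()] with a current bond.
#' @return The updated state (unchanged, with a warning, when the bond is not
#'   eligible or no compatible geometry with vacancies exists).
#' @export
switch_geometry <- function(s) {
  if (is.na(s$current_bond)) {
    warning("switch geometry: subject must be a bond")
    return(s)
  }
  m <- s$molecule
  bf <- m$bonds$from[s$current_bond]; bt <- m$bonds$to[s$current_bond]
  bord <- m$bonds$order[s$current_bond]
  deg_f <- length(neighbours(m, bf))
  deg_t <- length(neighbours(m, bt))
  if (!xor(deg_f == 1, deg_t == 1)) {
    warning("switch geometry: exactly one end of the bond must be terminal")
    return(s)
  }
  term <- if (deg_f == 1) bf else bt
  centre <- if (deg_f == 1) bt else bf
  orig <- bearing(m$atoms$x[term] - m$atoms$x[centre],
                  m$atoms$y[term] - m$atoms$y[centre])
  len <- atom_dist(m, centre, term)

  # geometry of the centre as if the selected bond were absent
  m2 <- remove_bonds(m, s$current_bond)
  rest <- bond_angles_at(m2, centre)
  if (!length(rest)) {
    vac <- c(0, 90, 180, 270)
  } else {
    vac <- NULL
    for (g in enumerate_plausible_geometries(m2, centre, bord)) {
      v <- match_template(rest, g)
      if (!is.null(v)) { vac <- v; break }
    }
    if (is.null(vac)) {
      warning("switch geometry: no compatible geometry")
      return(s)
    }
  }
  viable <- vac[abs_angle_diff(vac, orig) > GEOM_TOL]
  if (!length(viable)) {
    warning("switch geometry: no available positions")
    return(s)
  }
  inc <- (viable - orig) %% 360
  target <- viable[which.min(inc)]
  m$atoms$x[term] <- m$atoms$x[centre] + len * cos(deg2rad(target))
  m$atoms$y[term] <- m$atoms$y[centre] + len * sin(deg2rad(target))
  s$molecule <- m
  s
}
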