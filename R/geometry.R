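# Geometry perception: the seven idealized geometry templates, the
# congestion function, template matching against existing bond bearings, and
# inference of plausible new-bond angles.
#
# The template angle sets are canonical choices (each defined up to a common
# rotation): the two tetrahedral variants are the familiar 120/60/60/120 and
# 60/120/60/120 wedge layouts, octa1 is the regular hexagonal ("regular
# octahedral") star and octa2 extends square planar with the two 45-degree
# diagonals, making the octahedral pair a superset of most other templates.
# They are kept in one table so they can be revised without touching any
# algorithm.

GEOMETRY_TEMPLATES <- list(
  linear        = c(0, 180),
  trigonal      = c(0, 120, 240),
  tetra1        = c(0, 120, 180, 240),
  tetra2        = c(0, 60, 180, 240),
  square_planar = c(0, 90, 180, 270),
  octa1         = c(0, 60, 120, 180, 240, 300),
  octa2         = c(0, 45, 90, 180, 225, 270)
)

# Matching and vacancy-degeneracy tolerance, degrees.
GEOM_TOL <- 2

#' The seven geometry templates
#'
#' @param name Template name: one of `linear`, `trigonal`, `tetra1`,
#'   `tetra2`, `square_planar`, `octa1`, `octa2`; omit for the full list.
#' @return A numeric vector of idealized bond directions in degrees (0 = +x,
#'   counter-clockwise), or the named list of all seven.
#' @export
geometry_template <- function(name) {
  if (missing(name)) return(GEOMETRY_TEMPLATES)
  name <- match.arg(name, names(GEOMETRY_TEMPLATES))
  GEOMETRY_TEMPLATES[[name]]
}

#' Bond bearings at an atom
#'
#' @param m A [molecule()].
#' @param atom Atom index.
#' @return Ascending vector of bearings (degrees in `[0, 360)`) from `atom`
#'   to each bonded neighbour.
#' @export
bond_angles_at <- function(m, atom) {
  nb <- neighbours(m, atom)
  if (!length(nb)) return(numeric(0))
  sort(bearing(m$atoms$x[nb] - m$atoms$x[atom],
               m$atoms$y[nb] - m$atoms$y[atom]))
}

#' Congestion at a point
#'
#' The congestion at (x, y) is the sum over every atom i of
#' `1 / (dist(i, point)^2 + 0.001)`: large near crowded regions, bounded (by
#' the 0.001 softening constant) even at zero distance. New atoms and
#' fragments are steered toward low-congestion positions.
#'
#' @param m A [molecule()].
#' @param x,y Point coordinates in Angstroms.
#' @return Non-negative congestion value (0 for an empty molecule).
#' @export
point_congestion <- function(m, x, y) {
  if (n_atoms(m) == 0) return(0)
  sum(1 / ((m$atoms$x - x)^2 + (m$atoms$y - y)^2 + 0.001))
}

#' Total congestion of a molecule
#'
#' Sum of `1 / (d^2 + 0.001)` over all unique atom pairs.
#'
#' @param m A [molecule()].
#' @return Non-negative value; 0 for molecules with fewer than two atoms.
#' @export
total_congestion <- function(m) {
  n <- n_atoms(m)
  if (n < 2) return(0)
  d2 <- (outer(m$atoms$x, m$atoms$x, `-`)^2 + outer(m$atoms$y, m$atoms$y, `-`)^2)
  sum(1 / (d2[upper.tri(d2)] + 0.001))
}

# Does the multiset {existing order, new order} look alkyne- or allene-like?
.sp_future <- function(existing_orders, new_order) {
  if (length(existing_orders) != 1) return(FALSE)
  s <- sort(c(existing_orders, new_order))
  identical(s, c(1L, 3L)) || identical(s, c(2L, 2L))
}

#' Enumerate plausible geometry templates for an atom
#'
#' Considers the element, the existing bond orders and the order of the bond
#' about to be added, and produces the ordered list of geometry-template
#' names worth trying (first = most plausible). Terminal carbon/nitrogen
#' heading for an alkyne- or allene-like pattern is linear; terminal atoms
#' outside the s- and p-blocks get the versatile octahedral pair; carbon with
#' all-single bonds gets trigonal, square planar and both tetrahedral
#' variants; and so on down the periodic-block rules.
#'
#' @param m A [molecule()].
#' @param atom Atom index.
#' @param new_order Order (0:4) of the prospective new bond.
#' @return Character vector of template names (never empty).
#' @export
enumerate_plausible_geometries <- function(m, atom, new_order = 1L) {
  el <- m$atoms$element[atom]
  nb <- neighbours(m, atom)
  orders <- vapply(nb, function(j) m$bonds$order[bond_between(m, atom, j)], integer(1))
  block <- element_block(el)
  new_order <- as.integer(new_order)

  if (length(nb) == 1) {
    if (el %in% c("C", "N") && .sp_future(orders, new_order)) return("linear")
    if (!identical(block, "s") && !identical(block, "p")) return(c("octa1", "octa2"))
    if (el %in% c("C", "N", "O")) return("trigonal")
    return(c("trigonal", "linear"))
  }

  if (length(nb) == 2) {
    ang <- bond_angles_at(m, atom)
    if (abs_angle_diff(ang[1] + 180, ang[2]) <= GEOM_TOL) {
      if (identical(block, "s") || identical(block, "p")) return("square_planar")
      return(c("octa1", "octa2"))
    }
  }

  if (!is_real_element(el)) return(c("trigonal", "square_planar"))
  if (identical(block, "s")) return(c("trigonal", "square_planar", "octa1", "octa2"))
  if (el == "C") {
    if (all(c(orders, new_order) == 1L))
      return(c("trigonal", "square_planar", "tetra1", "tetra2"))
    return("trigonal")
  }
  if (identical(block, "p")) {
    if (pblock_period(el) <= 4) return(c("trigonal", "tetra1", "tetra2", "square_planar"))
    return(names(GEOMETRY_TEMPLATES))
  }
  c("octa1", "octa2")
}

#' Match existing bond bearings against a geometry template
#'
#' Tries every seed rotation that superimposes one existing bearing onto one
#' template slot (and the template's mirror image), accepting a rotation when
#' all existing bearings land on distinct slots within `tolerance`. The
#' unoccupied slots of each accepted rotation are the vacant bond directions;
#' vacancies duplicated across rotations (within `tolerance`) are collapsed,
#' as are vacancies indistinguishable from an existing bearing.
#'
#' @param existing Numeric vector of existing bond bearings (degrees).
#' @param template A template name or a numeric slot vector.
#' @param tolerance Angular tolerance in degrees (default 2).
#' @return `NULL` when the bearings cannot be matched; otherwise the sorted
#'   vector of vacancy angles (possibly empty when the template is full).
#' @export
match_template <- function(existing, template, tolerance = GEOM_TOL) {
  slots <- if (is.character(template)) geometry_template(template) else template
  if (length(existing) > length(slots)) return(NULL)
  if (!length(existing)) return(sort(norm_angle(slots)))
  vac <- numeric(0)
  matched <- FALSE
  for (mirror in c(FALSE, TRUE)) {
    sl <- if (mirror) norm_angle(-slots) else slots
    for (i in seq_along(existing)) {
      for (j in seq_along(sl)) {
        rot <- existing[i] - sl[j]
        rs <- norm_angle(sl + rot)
        cost <- abs(outer(existing, rs, abs_angle_diff))
        assign <- greedy_assign(cost, tol = tolerance)
        if (is.null(assign)) next
        matched <- TRUE
        vac <- c(vac, rs[-assign])
      }
    }
  }
  if (!matched) return(NULL)
  vac <- dedupe_angles(vac, tol = tolerance)
  keep <- vapply(vac, function(v) all(abs_angle_diff(existing, v) > tolerance), logical(1))
  sort(vac[keep])
}

# Circular midpoints between consecutive sorted bearings ("median-cut").
median_cut_angles <- function(angles) {
  a <- sort(norm_angle(angles))
  n <- length(a)
  if (n == 1) return(norm_angle(a + 180))
  gaps <- (a[c(2:n, 1)] - a) %% 360
  sort(norm_angle(a + gaps / 2))
}

#' Propose angles for a new bond at an atom
#'
#' The new-bond-angle inference sequence: an isolated atom offers the four
#' axis-aligned directions; otherwise the plausible geometry templates are
#' tried in order and the first that matches the existing bearings supplies
#' its vacancy angles; otherwise the fallback is the median-cut angles, the
#' circular midpoints between consecutive existing bearings (the full-valence
#' and irregular-geometry behaviour).
#'
#' @param m A [molecule()].
#' @param atom Atom index.
#' @param new_order Order (0:4) of the prospective bond.
#' @return Sorted vector of candidate bearings in degrees (never empty).
#' @export
propose_new_bond_angles <- function(m, atom, new_order = 1L) {
  angles <- bond_angles_at(m, atom)
  if (!length(angles)) return(c(0, 90, 180, 270))
  for (g in enumerate_plausible_geometries(m, atom, new_order)) {
    v <- match_template(angles, g)
    if (!is.null(v) && length(v)) return(v)
  }
  median_cut_angles(angles)
}

#' Refit the bonds at an atom to a geometry template
#'
#' If the existing bearings already match the template in some rotation the
#' molecule is returned unchanged. Otherwise every pairwise seed — one
#' existing bond superimposed on one template slot, for the template and its
#' mirror — is tried: the remaining bonds are snapped to the nearest distinct
#' slots, bonds that are part of a ring system must not move (their slot must
#' already coincide within tolerance), and the assignment with the smallest
#' overall angular displacement wins (ties prefer the non-mirrored template,
#' then the lowest seed slot). Each moved neighbour carries its whole acyclic
#' branch rigidly.
#'
#' @param m A [molecule()].
#' @param atom Atom index with at least one neighbour.
#' @param template Template name or slot vector.
#' @param tolerance Angular tolerance in degrees.
#' @return The refitted molecule, or `NULL` when every assignment would
#'   require moving a ring bond.
#' @export
refit_to_geometry <- function(m, atom, template, tolerance = GEOM_TOL) {
  slots <- if (is.character(template)) geometry_template(template) else template
  nb <- neighbours(m, atom)
  if (!length(nb)) stop("atom ", atom, " has no bonds to refit")
  if (length(nb) > length(slots)) return(NULL)
  angles <- bearing(m$atoms$x[nb] - m$atoms$x[atom], m$atoms$y[nb] - m$atoms$y[atom])
  if (!is.null(match_template(angles, slots, tolerance))) return(m)

  ring <- ring_bond_flags(m)
  nb_ring <- vapply(nb, function(j) ring[bond_between(m, atom, j)], logical(1))

  best <- NULL
  for (mirror in c(FALSE, TRUE)) {
    sl <- if (mirror) norm_angle(-slots) else slots
    for (i in seq_along(angles)) {
      for (j in seq_along(sl)) {
        rot <- angles[i] - sl[j]
        rs <- norm_angle(sl + rot)
        cost <- abs(outer(angles, rs, abs_angle_diff))
        assign <- greedy_assign(cost)
        if (is.null(assign)) next
        deltas <- angle_diff(angles, rs[assign])
        if (any(nb_ring & abs(deltas) > tolerance)) next
        disp <- sum(abs(deltas))
        if (is.null(best) || disp < best$disp - 1e-9) {
          best <- list(disp = disp, deltas = deltas)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  for (k in seq_along(nb)) {
    if (nb_ring[k] || abs(best$deltas[k]) < 1e-9) next
    br <- branch_atoms(m, atom, nb[k])
    br <- setdiff(br, atom)
    m <- rotate_coords(m, br, m$atoms$x[atom], m$atoms$y[atom], best$deltas[k])
  }
  m
}
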