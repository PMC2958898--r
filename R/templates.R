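# Template fragments. A template is a molecule fragment that may carry
# guide atoms: "*" placeholders marking the intended attachment direction
# and distance, deleted after grafting. A minimal built-in set ships with
# the package; user libraries are ordinary SD files, one record per
# template, guide atoms flagged by the "*" atom symbol.

#' Construct a template from a molecule
#'
#' @param fragment A [molecule()]; atoms with element `"*"` are treated as
#'   guide atoms.
#' @return An object of class `template` with fields `fragment` and `guides`
#'   (guide atom indices).
#' @export
as_template <- function(fragment) {
  structure(list(
    fragment = fragment,
    guides = which(fragment$atoms$element == "*")
  ), class = "template")
}

#' @export
print.template <- function(x, ...) {
  cat(sprintf("template: %d atoms (%d guides), %d bonds\n",
              n_atoms(x$fragment), length(x$guides), n_bonds(x$fragment)))
  invisible(x)
}

# Regular n-gon of carbon atoms with the default bond length.
ring_molecule <- function(n, orders = rep(1L, n)) {
  r <- DEFAULT_BOND_LENGTH / (2 * sin(pi / n))
  th <- 90 + (seq_len(n) - 1) * 360 / n  # first atom at the top
  m <- molecule(rep("C", n), x = r * cos(deg2rad(th)), y = r * sin(deg2rad(th)))
  for (i in seq_len(n)) m <- add_bond(m, i, i %% n + 1, orders[i])
  m
}

benzene_molecule <- function() ring_molecule(6, orders = c(2L, 1L, 2L, 1L, 2L, 1L))

cyclopentadiene_molecule <- function() ring_molecule(5, orders = c(2L, 1L, 2L, 1L, 1L))

naphthalene_molecule <- function() {
  m <- benzene_molecule()
  t <- graft_bond_connection(m, c(1, 2), as_template(benzene_molecule()))
  for (cand in t) if (n_atoms(cand) == 10 && n_bonds(cand) == 11) return(cand)
  stop("internal: naphthalene construction failed")
}

# Acetyl CH3-C(=O)- : trigonal carbonyl carbon at the origin.
acetyl_molecule <- function() {
  L <- DEFAULT_BOND_LENGTH
  m <- molecule(c("C", "O", "C"),
                x = c(0, L * cos(deg2rad(120)), L * cos(deg2rad(240))),
                y = c(0, L * sin(deg2rad(120)), L * sin(deg2rad(240))))
  m <- add_bond(m, 1, 2, 2L)
  add_bond(m, 1, 3, 1L)
}

# Carboxyl -C(=O)OH.
carboxyl_molecule <- function() {
  m <- acetyl_molecule()
  m$atoms$element[3] <- "O"
  m
}

.BUILTIN_TEMPLATES <- c("cyclopropane", "cyclobutane", "cyclopentane",
                        "cyclohexane", "cycloheptane", "cyclooctane",
                        "benzene", "cyclopentadiene", "naphthalene",
                        "acetyl", "carboxyl")

#' Built-in template library
#'
#' A minimal default set: carbocycles C3 through C8, benzene,
#' cyclopentadiene, naphthalene, and the acetyl and carboxyl groups.
#'
#' @param name Template name; omit to list the available names.
#' @return A `template`, or the character vector of names.
#' @export
built_in_template <- function(name) {
  if (missing(name)) return(.BUILTIN_TEMPLATES)
  name <- match.arg(name, .BUILTIN_TEMPLATES)
  frag <- switch(name,
    cyclopropane = ring_molecule(3),
    cyclobutane = ring_molecule(4),
    cyclopentane = ring_molecule(5),
    cyclohexane = ring_molecule(6),
    cycloheptane = ring_molecule(7),
    cyclooctane = ring_molecule(8),
    benzene = benzene_molecule(),
    cyclopentadiene = cyclopentadiene_molecule(),
    naphthalene = naphthalene_molecule(),
    acetyl = acetyl_molecule(),
    carboxyl = carboxyl_molecule()
  )
  as_template(frag)
}

#' Excise a template from the current sketch
#'
#' The subject atoms define a substructure. When they form whole connected
#' components the template is that substructure verbatim, with no guides.
#' Otherwise every atom immediately connected to a subject atom is also
#' included, converted into a `"*"` guide placeholder (bonds between two
#' boundary atoms are not carried over).
#'
#' @param s A [sketch_state()] with a non-empty subject.
#' @return A `template`.
#' @export
create_template <- function(s) {
  subj <- subject_atoms(s)
  if (!length(subj)) stop("create template: empty subject")
  m <- s$molecule
  boundary <- setdiff(unique(unlist(lapply(subj, neighbours, m = m))), subj)
  keep <- c(sort(subj), sort(boundary))
  frag <- molecule()
  a <- m$atoms
  for (i in keep) {
    bd <- i %in% boundary
    frag <- add_atom(frag, if (bd) "*" else a$element[i], a$x[i], a$y[i],
                     charge = if (bd) 0L else a$charge[i],
                     unpaired = if (bd) 0L else a$unpaired[i],
                     isotope = if (bd) NA_integer_ else a$isotope[i],
                     hydrogens = if (bd) NA_integer_ else a$hydrogens[i])
  }
  map <- match(seq_len(n_atoms(m)), keep)
  b <- m$bonds
  for (k in seq_len(n_bonds(m))) {
    f <- map[b$from[k]]; t <- map[b$to[k]]
    if (is.na(f) || is.na(t)) next
    if (b$from[k] %in% boundary && b$to[k] %in% boundary) next
    frag <- add_bond(frag, f, t, b$order[k], b$stereo[k])
  }
  as_template(frag)
}

#' Read and write template libraries as SD files
#'
#' One record per template; guide atoms are flagged by the atom symbol `"*"`
#' (the symbol `"A"` is also accepted on input).
#'
#' @param text SD file contents or path (for reading).
#' @return `read_template_library()`: a list of `template`s.
#' @export
read_template_library <- function(text) {
  lapply(read_sdf(text), as_template)
}

#' @rdname read_template_library
#' @param templates A list of `template`s (for writing).
#' @return `write_template_library()`: the SD text.
#' @export
write_template_library <- function(templates) {
  write_sdf(lapply(templates, `[[`, "fragment"))
}
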