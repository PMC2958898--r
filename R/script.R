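# Script-driven replay. A script is a list of steps; each step may set the
# subject (selection, current atom, or current bond), then apply one action
# with named parameters. Multi-result actions (grafts) expose their ranked
# candidate list and the step's `result` index (1-based, default 1) selects
# one. Replay is fully deterministic.
#
# On disk a script is JSON: {"steps": [{"select": [1,2], "action":
# "set_bond_order", "params": {"order": 2}}, ...]}. Subject indices refer to
# atom order in the evolving molecule; deletions and merges renumber atoms,
# which scripts must account for.

.SCRIPT_ACTIONS <- c(
  "add_atom", "set_element", "set_charge", "set_unpaired", "set_hydrogens",
  "set_isotope", "set_bond_order", "set_stereo_style", "connect",
  "disconnect", "delete", "merge", "move", "scale", "scale_bond", "flip",
  "rotate", "new_bond_order", "new_bond_style", "new_bond_geometry",
  "set_geometry", "switch_geometry", "graft", "copy", "paste"
)

apply_action <- function(s, action, params, env) {
  p <- function(name, default = NULL) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  switch(action,
    add_atom = add_atom_primitive(s, p("element", "C")),
    set_element = set_atom_property(s, "element", p("value")),
    set_charge = set_atom_property(s, "charge", p("value")),
    set_unpaired = set_atom_property(s, "unpaired", p("value")),
    set_hydrogens = set_atom_property(s, "hydrogens", p("value")),
    set_isotope = set_atom_property(s, "isotope", p("value")),
    set_bond_order = set_bond_order(s, p("order", 1L)),
    set_stereo_style = set_stereo_style(s, p("style")),
    connect = connect_atoms(s),
    disconnect = disconnect_atoms(s),
    delete = delete_subject(s, p("mode", "atoms")),
    merge = merge_atoms(s),
    move = move_atoms(s, p("direction"), p("extent", "small_nudge")),
    scale = scale_atoms(s, p("mode", "grow")),
    scale_bond = scale_bond(s, p("mode", "grow")),
    flip = flip_atoms(s, p("axis", "vertical")),
    rotate = rotate_atoms(s, p("increment", 15)),
    new_bond_order = new_bond_with_order(s, p("order", 1L)),
    new_bond_style = new_bond_with_style(s, p("style")),
    new_bond_geometry = new_bond_with_geometry(s, p("template")),
    set_geometry = set_geometry(s, p("template")),
    switch_geometry = switch_geometry(s),
    copy = { env$clipboard <- create_template(s); s },
    stop("unregistered action: ", action)
  )
}

resolve_template <- function(spec, env) {
  if (inherits(spec, "template")) return(spec)
  if (is.character(spec)) {
    if (spec == "clipboard") {
      if (is.null(env$clipboard)) stop("clipboard is empty")
      return(env$clipboard)
    }
    if (spec %in% built_in_template()) return(built_in_template(spec))
    if (!is.null(env$library[[spec]])) return(env$library[[spec]])
    stop("unknown template: ", spec)
  }
  stop("template must be a name or a template object")
}

#' Replay a script of primitive invocations
#'
#' @param steps A list of steps (see the package vignette), or the path to
#'   (or text of) a JSON script file.
#' @param initial Starting [molecule()] (empty by default).
#' @param templates Optional named list of extra `template`s, consulted after
#'   the built-in library.
#' @param verbose Log each step's action, subject resolution and candidate
#'   counts via `message()`.
#' @return The final [sketch_state()]; errors abort with the step number.
#' @export
run_script <- function(steps, initial = molecule(), templates = list(),
                       verbose = FALSE) {
  if (is.character(steps)) steps <- read_script(steps)
  if (!is.null(steps$steps)) steps <- steps$steps
  s <- sketch_state(initial)
  env <- new.env(parent = emptyenv())
  env$clipboard <- NULL
  env$library <- templates
  for (k in seq_along(steps)) {
    st <- steps[[k]]
    ok <- try({
      # a step that names any subject field replaces the whole subject;
      # selection and a current atom/bond may be given together (the current
      # object then supplies the centre for flips/rotations/scales)
      if (isTRUE(st$clear) || !is.null(st$select) || !is.null(st$current_atom) ||
          !is.null(st$current_bond)) {
        s <- clear_subject(s)
      }
      if (!is.null(st$select)) s <- set_selection(s, unlist(st$select))
      if (!is.null(st$current_atom)) s <- set_current_atom(s, st$current_atom)
      if (!is.null(st$current_bond)) {
        cb <- unlist(st$current_bond)
        s <- set_current_bond(s, cb[1], cb[2])
      }
      if (!is.null(st$action)) {
        action <- st$action
        if (!action %in% .SCRIPT_ACTIONS) stop("unregistered action: ", action)
        if (action %in% c("graft", "paste")) {
          tspec <- if (action == "paste") "clipboard" else st$template
          tmpl <- resolve_template(tspec, env)
          results <- graft(s, tmpl)
          idx <- if (!is.null(st$result)) st$result else 1L
          if (verbose)
            message(sprintf("step %d: %s '%s' -> %d candidates, taking %d",
                            k, action, if (is.character(tspec)) tspec else "template",
                            length(results), idx))
          if (idx < 1 || idx > length(results))
            stop("result index ", idx, " out of range (", length(results),
                 " candidates)")
          s <- clear_subject(sketch_state(results[[idx]]$molecule))
        } else {
          if (verbose)
            message(sprintf("step %d: %s [subject: %s]", k, action,
                            paste(subject_atoms(s), collapse = " ")))
          s <- apply_action(s, action, st$params, env)
        }
      }
      TRUE
    }, silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("script step ", k, ": ", attr(ok, "condition")$message, call. = FALSE)
  }
  s
}

#' @rdname run_script
#' @param path Path to (or text of) a JSON script.
#' @export
read_script <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Element- and order-labelled graph isomorphism
#'
#' Tests whether two sketches share the same molecular graph — atoms matched
#' by element, bonds by order — ignoring coordinates and stereo annotations.
#' This is the looser comparison used to check a replayed drawing against a
#' reference connection table; [structures_equivalent()] is the strict
#' sketch-level test.
#'
#' @param a,b [molecule()]s.
#' @return `TRUE` or `FALSE`.
#' @export
isomorphic_sketch <- function(a, b) {
  if (n_atoms(a) != n_atoms(b) || n_bonds(a) != n_bonds(b)) return(FALSE)
  if (!identical(sort(a$atoms$element), sort(b$atoms$element))) return(FALSE)
  if (!identical(sort(a$bonds$order), sort(b$bonds$order))) return(FALSE)
  pal <- sort(unique(c(a$atoms$element, b$atoms$element)))
  ga <- mol_graph(a); gb <- mol_graph(b)
  igraph::isomorphic(
    ga, gb, method = "vf2",
    vertex.color1 = match(a$atoms$element, pal),
    vertex.color2 = match(b$atoms$element, pal),
    edge.color1 = a$bonds$order + 1L,
    edge.color2 = b$bonds$order + 1L
  )
}
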