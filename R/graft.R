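# Template grafting: fusing a template fragment onto the sketch by atom
# overlay, bond alignment, bridging bond, or guide-atom mapping. Every mode
# emits a list of candidate molecules; the dispatcher pools them, removes
# equivalent duplicates, scores and ranks.

# ---- fragment transforms ---------------------------------------------------

# Mirror image: invert x; inclined and declined wedges are interchanged.
mirror_molecule <- function(m) {
  m$atoms$x <- -m$atoms$x
  st <- m$bonds$stereo
  m$bonds$stereo[st == "inclined"] <- "declined"
  m$bonds$stereo[st == "declined"] <- "inclined"
  m
}

translate_molecule <- function(m, dx, dy) {
  m$atoms$x <- m$atoms$x + dx
  m$atoms$y <- m$atoms$y + dy
  m
}

rotate_molecule <- function(m, cx, cy, deg) {
  rotate_coords(m, seq_len(n_atoms(m)), cx, cy, deg)
}

# Fragment with guide atoms removed.
strip_guides <- function(t) {
  if (!length(t$guides)) return(t$fragment)
  m <- remove_atoms(t$fragment, t$guides)
  attr(m, "atom_map") <- NULL
  m
}

# Append fragment atoms/bonds to m; returns list(mol, input_ids, frag_ids).
# Both inputs are valid molecules with disjoint index spaces, so the frames
# are concatenated wholesale.
combine_fragments <- function(m, frag) {
  off <- n_atoms(m)
  m$atoms <- cols_bind(m$atoms, frag$atoms)
  if (n_bonds(frag)) {
    fb <- frag$bonds
    fb$from <- fb$from + off
    fb$to <- fb$to + off
    m$bonds <- cols_bind(m$bonds, fb)
  }
  list(mol = m, input_ids = seq_len(off), frag_ids = off + seq_len(n_atoms(frag)))
}

# Merge cross-partition overlaps and annotate the candidate with
# merged_count, guide_count, and the bonds that were not present pre-graft.
finalize_candidate <- function(input, combined, input_ids, frag_ids,
                               guide_count = 0L) {
  res <- merge_overlapping(combined, input_ids, frag_ids, OVERLAP_THRESHOLD)
  map <- attr(res, "atom_map")
  merged <- attr(res, "merged_count")
  # pre-existing bonds: images of the input structure's bonds
  old_keys <- character(0)
  if (n_bonds(input)) {
    f <- map[input$bonds$from]; t <- map[input$bonds$to]
    old_keys <- paste(pmin(f, t), pmax(f, t))
  }
  b <- res$bonds
  new_flag <- !(paste(pmin(b$from, b$to), pmax(b$from, b$to)) %in% old_keys)
  attr(res, "merged_count") <- merged
  attr(res, "guide_count") <- as.integer(guide_count)
  attr(res, "new_bonds") <- which(new_flag)
  attr(res, "atom_map") <- map
  res
}

# ---- grafting modes --------------------------------------------------------

#' Graft a template with no connections
#'
#' With an empty subject the fragment is simply placed clear of the existing
#' content — to the right, centred vertically on the existing bounding box,
#' with a default-bond-length gap (at the origin on an empty canvas). All
#' distinct rotations in increments of 30 and 45 degrees are offered.
#'
#' @param m The current [molecule()].
#' @param t A `template` (guide atoms are stripped).
#' @return List of candidate molecules.
#' @export
graft_no_connection <- function(m, t) {
  frag <- strip_guides(t)
  if (!n_atoms(frag)) return(list())
  rots <- sort(unique(c(seq(0, 330, by = 30), seq(0, 315, by = 45))))
  out <- list()
  for (r in rots) {
    fr <- rotate_molecule(frag, mean(frag$atoms$x), mean(frag$atoms$y), r)
    if (n_atoms(m) == 0) {
      fr <- translate_molecule(fr, -mean(fr$atoms$x), -mean(fr$atoms$y))
    } else {
      dx <- (max(m$atoms$x) + DEFAULT_BOND_LENGTH) - min(fr$atoms$x)
      dy <- (min(m$atoms$y) + max(m$atoms$y)) / 2 - (min(fr$atoms$y) + max(fr$atoms$y)) / 2
      fr <- translate_molecule(fr, dx, dy)
    }
    cmb <- combine_fragments(m, fr)
    out[[length(out) + 1]] <- finalize_candidate(m, cmb$mol, cmb$input_ids, cmb$frag_ids)
  }
  out
}

#' Graft a template onto a single subject atom
#'
#' For the template and its mirror image, and every fragment atom N: direct
#' connection superimposes N on the subject atom and rotates the fragment by
#' `theta1 - theta2 + 180` over every pair of candidate bond angles (from the
#' new-bond inference on both sides); bridge connection instead places N a
#' default bond length out along each `theta1` and joins the two atoms with a
#' single bond. Overlapping atoms are merged.
#'
#' @param m The current [molecule()].
#' @param subject Subject atom index.
#' @param t A `template` (guide atoms are stripped).
#' @return List of candidate molecules.
#' @export
graft_atom_connection <- function(m, subject, t) {
  frag0 <- strip_guides(t)
  if (!n_atoms(frag0)) return(list())
  th1s <- propose_new_bond_angles(m, subject, 1L)
  sx <- m$atoms$x[subject]; sy <- m$atoms$y[subject]
  out <- list()
  for (mir in c(FALSE, TRUE)) {
    frag <- if (mir) mirror_molecule(frag0) else frag0
    for (N in seq_len(n_atoms(frag))) {
      th2s <- propose_new_bond_angles(frag, N, 1L)
      for (th1 in th1s) for (th2 in th2s) {
        rot <- th1 - th2 + 180
        # direct: N on the subject atom
        fr <- translate_molecule(frag, sx - frag$atoms$x[N], sy - frag$atoms$y[N])
        fr <- rotate_molecule(fr, sx, sy, rot)
        cmb <- combine_fragments(m, fr)
        out[[length(out) + 1]] <-
          finalize_candidate(m, cmb$mol, cmb$input_ids, cmb$frag_ids)
        # bridge: N at the end of a projected default-length bond
        px <- sx + DEFAULT_BOND_LENGTH * cos(deg2rad(th1))
        py <- sy + DEFAULT_BOND_LENGTH * sin(deg2rad(th1))
        fr <- translate_molecule(frag, px - frag$atoms$x[N], py - frag$atoms$y[N])
        fr <- rotate_molecule(fr, px, py, rot)
        cmb <- combine_fragments(m, fr)
        mol <- add_bond(cmb$mol, subject, cmb$frag_ids[N], 1L)
        out[[length(out) + 1]] <-
          finalize_candidate(m, mol, cmb$input_ids, cmb$frag_ids)
      }
    }
  }
  out
}

#' Graft a template onto a subject bond
#'
#' For the template and its mirror, every fragment bond is superimposed on
#' the subject bond — centroids coincident, bonds parallel or anti-parallel —
#' and the matched atoms are merged, the coordinates of the input structure
#' always retained. Remaining overlaps are merged as usual.
#'
#' @param m The current [molecule()].
#' @param subject Length-2 vector of bonded atom indices.
#' @param t A `template` (guide atoms are stripped).
#' @return List of candidate molecules.
#' @export
graft_bond_connection <- function(m, subject, t) {
  frag0 <- strip_guides(t)
  if (!n_bonds(frag0)) return(list())
  a1 <- subject[1]; a2 <- subject[2]
  bx <- mean(m$atoms$x[c(a1, a2)]); by <- mean(m$atoms$y[c(a1, a2)])
  out <- list()
  for (mir in c(FALSE, TRUE)) {
    frag <- if (mir) mirror_molecule(frag0) else frag0
    for (N in seq_len(n_bonds(frag))) {
      n1 <- frag$bonds$from[N]; n2 <- frag$bonds$to[N]
      for (par in c(TRUE, FALSE)) {
        tgt <- if (par) c(a1, a2) else c(a2, a1)
        fr <- translate_molecule(frag,
                                 bx - mean(frag$atoms$x[c(n1, n2)]),
                                 by - mean(frag$atoms$y[c(n1, n2)]))
        want <- bearing(m$atoms$x[tgt[2]] - m$atoms$x[tgt[1]],
                        m$atoms$y[tgt[2]] - m$atoms$y[tgt[1]])
        have <- bearing(fr$atoms$x[n2] - fr$atoms$x[n1],
                        fr$atoms$y[n2] - fr$atoms$y[n1])
        fr <- rotate_molecule(fr, bx, by, want - have)
        # matched atoms take the input structure's coordinates exactly
        fr$atoms$x[c(n1, n2)] <- m$atoms$x[tgt]
        fr$atoms$y[c(n1, n2)] <- m$atoms$y[tgt]
        cmb <- combine_fragments(m, fr)
        out[[length(out) + 1]] <-
          finalize_candidate(m, cmb$mol, cmb$input_ids, cmb$frag_ids)
      }
    }
  }
  out
}

#' Graft a template onto several subject atoms
#'
#' For the template and its mirror, and every ordered pair of fragment atoms
#' (N1, N2): N1 is translated onto the first subject atom and the fragment
#' rotated about it so the N1-N2 direction matches the first two subject
#' atoms. The graft is rejected unless N2 then overlaps the second subject
#' atom and every remaining subject atom overlaps some fragment atom; no
#' rescaling is performed. Survivors are merged.
#'
#' @param m The current [molecule()].
#' @param subject Atom indices (>= 2, ascending; not a bonded pair).
#' @param t A `template` (guide atoms are stripped).
#' @return List of candidate molecules (possibly empty).
#' @export
graft_multi_connection <- function(m, subject, t) {
  frag0 <- strip_guides(t)
  if (n_atoms(frag0) < 2) return(list())
  s1 <- subject[1]; s2 <- subject[2]
  sx <- m$atoms$x[s1]; sy <- m$atoms$y[s1]
  dir_s <- bearing(m$atoms$x[s2] - sx, m$atoms$y[s2] - sy)
  rest <- subject[-(1:2)]
  out <- list()
  for (mir in c(FALSE, TRUE)) {
    frag <- if (mir) mirror_molecule(frag0) else frag0
    for (N1 in seq_len(n_atoms(frag))) {
      for (N2 in seq_len(n_atoms(frag))) {
        if (N1 == N2) next
        fr <- translate_molecule(frag, sx - frag$atoms$x[N1], sy - frag$atoms$y[N1])
        have <- bearing(fr$atoms$x[N2] - sx, fr$atoms$y[N2] - sy)
        fr <- rotate_molecule(fr, sx, sy, dir_s - have)
        d2 <- sqrt((fr$atoms$x[N2] - m$atoms$x[s2])^2 + (fr$atoms$y[N2] - m$atoms$y[s2])^2)
        if (d2 >= OVERLAP_THRESHOLD) next
        ok <- all(vapply(rest, function(si) {
          min(sqrt((fr$atoms$x - m$atoms$x[si])^2 + (fr$atoms$y - m$atoms$y[si])^2)) <
            OVERLAP_THRESHOLD
        }, logical(1)))
        if (!ok) next
        cmb <- combine_fragments(m, fr)
        out[[length(out) + 1]] <-
          finalize_candidate(m, cmb$mol, cmb$input_ids, cmb$frag_ids)
      }
    }
  }
  out
}

# Guide-merge helper: fold guide atoms into their subject atoms (rewiring the
# guides' bonds), then merge remaining overlaps. `pairs` is a 2-column matrix
# of (subject index, guide index) in the combined molecule.
absorb_guides <- function(input, combined, input_ids, frag_ids, pairs) {
  m <- combined
  for (k in seq_len(nrow(pairs))) {
    m <- merge_pair(m, pairs[k, 1], pairs[k, 2])
    map <- attr(m, "atom_map")
    map[pairs[k, 2]] <- map[pairs[k, 1]]
    if (k < nrow(pairs)) pairs[(k + 1):nrow(pairs), ] <- map[pairs[(k + 1):nrow(pairs), ]]
    input_ids <- unique(map[input_ids])
    frag_ids <- setdiff(unique(map[frag_ids]), input_ids)
  }
  finalize_candidate(input, m, input_ids, frag_ids, guide_count = nrow(pairs))
}

#' Graft a template using its guide atoms
#'
#' Dispatches on the guide configuration:
#' one subject atom and one single-neighbour guide — the subject's projection
#' angles are matched to the guide-to-neighbour direction, the bond distance
#' taken from the guide bond, the guide deleted and its bond rewired to the
#' subject; a subject bond and one single-neighbour guide — four base
#' permutations (mirror x parallel/anti-parallel), bifurcating over the two
#' possible bond lengths when the matched bonds differ; one subject atom and
#' one multi-neighbour guide — the guide's median angle is aligned with the
#' subject's projection angle; k subject atoms and k guides — the guides are
#' aligned onto the subjects as in [graft_multi_connection()]. Mirrors are
#' always tried; guides are deleted from every result.
#'
#' @param m The current [molecule()].
#' @param subject Subject atom indices.
#' @param t A `template` with at least one guide atom.
#' @return List of candidate molecules (empty when no guide mode applies).
#' @export
graft_with_guides <- function(m, subject, t) {
  ng <- length(t$guides)
  if (!ng) return(list())
  frag_full <- t$fragment
  g <- t$guides[1]
  g_nb <- neighbours(frag_full, g)
  subj_bonded <- length(subject) == 2 && !is.na(bond_between(m, subject[1], subject[2]))

  out <- list()
  if (ng == 1 && length(subject) == 1 && length(g_nb) == 1) {
    out <- c(out, .guide_atom_mode(m, subject, frag_full, g, g_nb))
  }
  if (ng == 1 && subj_bonded && length(g_nb) == 1) {
    out <- c(out, .guide_bond_mode(m, subject, frag_full, g, g_nb))
  }
  if (ng == 1 && length(subject) == 1 && length(g_nb) > 1) {
    out <- c(out, .guide_median_mode(m, subject, frag_full, g, g_nb))
  }
  if (length(subject) >= 2 && !subj_bonded && ng == length(subject)) {
    out <- c(out, .guide_multi_mode(m, subject, t))
  }
  out
}

.guide_atom_mode <- function(m, subject, frag_full, g, gn) {
  th1s <- propose_new_bond_angles(m, subject, 1L)
  sx <- m$atoms$x[subject]; sy <- m$atoms$y[subject]
  out <- list()
  for (mir in c(FALSE, TRUE)) {
    frag <- if (mir) mirror_molecule(frag_full) else frag_full
    gang <- bearing(frag$atoms$x[gn] - frag$atoms$x[g],
                    frag$atoms$y[gn] - frag$atoms$y[g])
    for (th1 in th1s) {
      fr <- translate_molecule(frag, sx - frag$atoms$x[g], sy - frag$atoms$y[g])
      fr <- rotate_molecule(fr, sx, sy, th1 - gang)
      cmb <- combine_fragments(m, fr)
      out[[length(out) + 1]] <- absorb_guides(
        m, cmb$mol, cmb$input_ids, cmb$frag_ids,
        cbind(subject, cmb$frag_ids[g])
      )
    }
  }
  out
}

.guide_bond_mode <- function(m, subject, frag_full, g, gn) {
  p <- subject[1]; q <- subject[2]
  len_s <- atom_dist(m, p, q)
  out <- list()
  for (mir in c(FALSE, TRUE)) {
    frag <- if (mir) mirror_molecule(frag_full) else frag_full
    len_t <- sqrt((frag$atoms$x[gn] - frag$atoms$x[g])^2 +
                  (frag$atoms$y[gn] - frag$atoms$y[g])^2)
    for (par in c(TRUE, FALSE)) {
      A <- if (par) p else q   # guide maps to A, its neighbour to B
      B <- if (par) q else p
      dirAB <- bearing(m$atoms$x[B] - m$atoms$x[A], m$atoms$y[B] - m$atoms$y[A])
      variants <- if (abs(len_t - len_s) > OVERLAP_THRESHOLD) c("input", "template")
                  else "input"
      for (vv in variants) {
        if (vv == "input") {
          # anchor the guide's neighbour on B; guide falls along B -> A
          fr <- translate_molecule(frag,
                                   m$atoms$x[B] - frag$atoms$x[gn],
                                   m$atoms$y[B] - frag$atoms$y[gn])
          have <- bearing(fr$atoms$x[g] - fr$atoms$x[gn], fr$atoms$y[g] - fr$atoms$y[gn])
          fr <- rotate_molecule(fr, m$atoms$x[B], m$atoms$y[B], (dirAB + 180) - have)
          mm <- m
        } else {
          # anchor the guide on A; the input atom B moves out to the
          # template's bond length
          fr <- translate_molecule(frag,
                                   m$atoms$x[A] - frag$atoms$x[g],
                                   m$atoms$y[A] - frag$atoms$y[g])
          have <- bearing(fr$atoms$x[gn] - fr$atoms$x[g], fr$atoms$y[gn] - fr$atoms$y[g])
          fr <- rotate_molecule(fr, m$atoms$x[A], m$atoms$y[A], dirAB - have)
          mm <- m
          mm$atoms$x[B] <- fr$atoms$x[gn]
          mm$atoms$y[B] <- fr$atoms$y[gn]
        }
        cmb <- combine_fragments(mm, fr)
        out[[length(out) + 1]] <- absorb_guides(
          mm, cmb$mol, cmb$input_ids, cmb$frag_ids,
          cbind(A, cmb$frag_ids[g])
        )
      }
    }
  }
  out
}

.guide_median_mode <- function(m, subject, frag_full, g, g_nb) {
  th1s <- propose_new_bond_angles(m, subject, 1L)
  sx <- m$atoms$x[subject]; sy <- m$atoms$y[subject]
  out <- list()
  for (mir in c(FALSE, TRUE)) {
    frag <- if (mir) mirror_molecule(frag_full) else frag_full
    angs <- bearing(frag$atoms$x[g_nb] - frag$atoms$x[g],
                    frag$atoms$y[g_nb] - frag$atoms$y[g])
    med <- bearing(sum(cos(deg2rad(angs))), sum(sin(deg2rad(angs))))
    for (th1 in th1s) {
      fr <- translate_molecule(frag, sx - frag$atoms$x[g], sy - frag$atoms$y[g])
      fr <- rotate_molecule(fr, sx, sy, th1 - med)
      cmb <- combine_fragments(m, fr)
      out[[length(out) + 1]] <- absorb_guides(
        m, cmb$mol, cmb$input_ids, cmb$frag_ids,
        cbind(subject, cmb$frag_ids[g])
      )
    }
  }
  out
}

.guide_multi_mode <- function(m, subject, t) {
  s1 <- subject[1]; s2 <- subject[2]
  sx <- m$atoms$x[s1]; sy <- m$atoms$y[s1]
  dir_s <- bearing(m$atoms$x[s2] - sx, m$atoms$y[s2] - sy)
  out <- list()
  for (mir in c(FALSE, TRUE)) {
    frag <- if (mir) mirror_molecule(t$fragment) else t$fragment
    guides <- t$guides
    for (g1 in guides) for (g2 in guides) {
      if (g1 == g2) next
      fr <- translate_molecule(frag, sx - frag$atoms$x[g1], sy - frag$atoms$y[g1])
      have <- bearing(fr$atoms$x[g2] - sx, fr$atoms$y[g2] - sy)
      fr <- rotate_molecule(fr, sx, sy, dir_s - have)
      # every guide must land on a distinct subject atom
      gd <- outer(guides, subject, function(gi, si)
        sqrt((fr$atoms$x[gi] - m$atoms$x[si])^2 + (fr$atoms$y[gi] - m$atoms$y[si])^2))
      assign <- greedy_assign(gd, tol = OVERLAP_THRESHOLD)
      if (is.null(assign)) next
      cmb <- combine_fragments(m, fr)
      pairs <- cbind(subject[assign], cmb$frag_ids[guides])
      out[[length(out) + 1]] <-
        absorb_guides(m, cmb$mol, cmb$input_ids, cmb$frag_ids, pairs)
    }
  }
  out
}

# ---- scoring and ranking ---------------------------------------------------

#' Score a grafted-template result
#'
#' Lower is better. The score is the sum of: the total congestion of the
#' molecule; +1 per atom merged due to positional overlap; +50 per clearly
#' sp3/sp2/sp-hybridised C, N, O, P or S atom that received a new bond more
#' than 5 degrees away from the ideal 120 (sp3/sp2) or 180 (sp) relative to
#' its pre-existing neighbours; +1000 per carbon or nitrogen with total bond
#' order of 5 or more; and -1 per guide atom involved in the grafting.
#'
#' @param g Result [molecule()].
#' @param merged_count Number of overlap merges performed.
#' @param guide_count Number of guide atoms consumed.
#' @param new_bonds Bond row indices of `g` that were absent before the
#'   graft (`NULL`: no angle-regularity term).
#' @return Numeric score.
#' @export
score_graft_result <- function(g, merged_count = 0L, guide_count = 0L,
                               new_bonds = NULL) {
  score <- total_congestion(g) + merged_count - guide_count

  # pentavalent carbon/nitrogen
  n <- n_atoms(g)
  tot <- numeric(n)
  if (n_bonds(g)) {
    bsum <- rowsum(c(g$bonds$order, g$bonds$order),
                   c(g$bonds$from, g$bonds$to))
    tot[as.integer(rownames(bsum))] <- bsum[, 1]
  }
  score <- score + 1000 * sum(g$atoms$element %in% c("C", "N") & tot >= 5)

  # irregular new-bond angles at clearly hybridised organic atoms
  if (length(new_bonds)) {
    nb_set <- new_bonds
    touched <- unique(c(g$bonds$from[nb_set], g$bonds$to[nb_set]))
    for (i in touched) {
      if (!g$atoms$element[i] %in% c("C", "N", "O", "P", "S")) next
      if (g$atoms$charge[i] != 0 || g$atoms$unpaired[i] != 0) next
      inc <- incident_bonds(g, i)
      orders <- g$bonds$order[inc]
      if (!length(orders)) next
      hyb <- if (sum(orders == 3) == 1 || sum(orders == 2) == 2) "sp"
        else if (sum(orders == 2) == 1) "sp2"
        else if (all(orders == 1)) "sp3"
        else NA_character_
      if (is.na(hyb)) next
      new_inc <- intersect(inc, nb_set)
      old_inc <- setdiff(inc, nb_set)
      if (!length(new_inc) || !length(old_inc)) next
      ideal <- if (hyb == "sp") 180 else 120
      other_end <- function(k) if (g$bonds$from[k] == i) g$bonds$to[k] else g$bonds$from[k]
      irregular <- FALSE
      for (kn in new_inc) {
        j <- other_end(kn)
        an <- bearing(g$atoms$x[j] - g$atoms$x[i], g$atoms$y[j] - g$atoms$y[i])
        for (ko in old_inc) {
          jo <- other_end(ko)
          ao <- bearing(g$atoms$x[jo] - g$atoms$x[i], g$atoms$y[jo] - g$atoms$y[i])
          if (abs(abs_angle_diff(an, ao) - ideal) > 5) irregular <- TRUE
        }
      }
      if (irregular) score <- score + 50
    }
  }
  score
}

#' Rank and filter graft candidates
#'
#' Removes equivalent duplicates (keeping the earliest generated), sorts by
#' ascending score (stable), and — when the best available score is below
#' 1000 — excludes every structure scoring 1000 or more.
#'
#' @param results List of `graft_result` objects.
#' @return The ordered, filtered list.
#' @export
rank_and_filter <- function(results) {
  if (!length(results)) return(results)
  # cheap invariants per candidate: equivalent sketches must agree exactly on
  # counts/labels/orders and elementwise (within 0.2) on sorted centred
  # coordinates, so most pairs are rejected without the full mapping
  sig <- lapply(results, function(r) {
    m <- r$molecule
    list(key = paste(n_atoms(m), n_bonds(m),
                     paste(sort(m$atoms$element), collapse = ""),
                     paste(sort(m$bonds$order), collapse = "")),
         sx = sort(m$atoms$x - mean(m$atoms$x)),
         sy = sort(m$atoms$y - mean(m$atoms$y)))
  })
  uniq <- list()
  usig <- list()
  for (k in seq_along(results)) {
    r <- results[[k]]
    dup <- FALSE
    for (j in seq_along(uniq)) {
      if (usig[[j]]$key != sig[[k]]$key) next
      if (max(abs(usig[[j]]$sx - sig[[k]]$sx)) > 0.2 ||
          max(abs(usig[[j]]$sy - sig[[k]]$sy)) > 0.2) next
      if (structures_equivalent(uniq[[j]]$molecule, r$molecule)) { dup <- TRUE; break }
    }
    if (!dup) {
      uniq[[length(uniq) + 1]] <- r
      usig[[length(usig) + 1]] <- sig[[k]]
    }
  }
  scores <- vapply(uniq, `[[`, numeric(1), "score")
  uniq <- uniq[order(scores)]
  scores <- sort(scores)
  if (length(scores) && scores[1] < 1000) uniq <- uniq[scores < 1000]
  uniq
}

# Wrap a candidate molecule (with finalize_candidate attributes) as a scored
# graft_result.
as_graft_result <- function(mol, mode) {
  merged <- attr(mol, "merged_count") %||% 0L
  guides <- attr(mol, "guide_count") %||% 0L
  newb <- attr(mol, "new_bonds")
  structure(list(
    molecule = mol,
    score = score_graft_result(mol, merged, guides, newb),
    merged_count = merged,
    guide_count = guides,
    mode = mode
  ), class = "graft_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.graft_result <- function(x, ...) {
  cat(sprintf("graft result (%s): score %.4f, %d merged, %d guides\n",
              x$mode, x$score, x$merged_count, x$guide_count))
  print(x$molecule)
  invisible(x)
}

#' Graft a template onto the sketch
#'
#' The dispatcher: when the template has guide atoms and a guide mode
#' applies, the guide modes generate the candidates; otherwise guides are
#' stripped and the subject shape picks the mode — empty subject: free
#' placement; one atom: atom connection; a bonded pair: bond connection; two
#' or more atoms otherwise: multiple connection. Candidates from all
#' applicable modes are pooled, deduplicated, scored and ranked (see
#' [rank_and_filter()]). The clipboard is just a single temporary template
#' sharing this path.
#'
#' @param s A [sketch_state()].
#' @param t A `template` (see [as_template()], [built_in_template()],
#'   [create_template()]).
#' @return Ordered list of `graft_result` objects (possibly empty).
#' @export
graft <- function(s, t) {
  m <- s$molecule
  subj <- subject_atoms(s)
  cands <- list()
  modes <- character(0)
  if (length(t$guides)) {
    gc <- graft_with_guides(m, subj, t)
    if (length(gc)) {
      cands <- gc
      modes <- rep("guides", length(gc))
    }
  }
  if (!length(cands)) {
    subj_bonded <- length(subj) == 2 && !is.na(bond_between(m, subj[1], subj[2]))
    if (length(subj) == 0) {
      cands <- graft_no_connection(m, t); mode <- "no_connection"
    } else if (length(subj) == 1) {
      cands <- graft_atom_connection(m, subj, t); mode <- "atom_connection"
    } else if (subj_bonded) {
      cands <- graft_bond_connection(m, subj, t); mode <- "bond_connection"
    } else {
      cands <- graft_multi_connection(m, subj, t); mode <- "multi_connection"
    }
    modes <- rep(mode, length(cands))
  }
  results <- mapply(as_graft_result, cands, modes, SIMPLIFY = FALSE)
  rank_and_filter(results)
}
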