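# Exoticness and overlap merging.
#
# When two atoms occupy (nearly) the same position, one must be retained and
# the other deleted with its bonds reassigned. The retained atom is the more
# "exotic" one — the one carrying more non-default properties — or the
# earlier-indexed one on a draw. The same rule picks the survivor among
# duplicate bonds created by the reassignment.

#' Atom exoticness
#'
#' One point for each non-default property: an element label other than
#' carbon; non-zero charge; any unpaired electrons; a non-default isotope; a
#' specific (non-automatic) hydrogen count.
#'
#' @param m A [molecule()].
#' @param i Atom index (vectorized).
#' @return Integer in 0..5.
#' @export
atom_exoticness <- function(m, i = seq_len(n_atoms(m))) {
  a <- m$atoms
  (a$element[i] != "C") + (a$charge[i] != 0) + (a$unpaired[i] > 0) +
    (!is.na(a$isotope[i])) + (!is.na(a$hydrogens[i]))
}

#' Bond exoticness
#'
#' One point each for a bond order other than 1 and for any stereochemical
#' assignment.
#'
#' @param m A [molecule()].
#' @param i Bond row index (vectorized).
#' @return Integer in 0..2.
#' @export
bond_exoticness <- function(m, i = seq_len(n_bonds(m))) {
  (m$bonds$order[i] != 1L) + (m$bonds$stereo[i] != "none")
}

# Merge atom `gone` into atom `keep`: reassign bonds, collapse duplicates
# (keeping the more exotic bond, earliest on a draw), delete `gone`.
# Returns the molecule with attr "atom_map".
merge_pair <- function(m, keep, gone) {
  b <- m$bonds
  b$from[b$from == gone] <- keep
  b$to[b$to == gone] <- keep
  m$bonds <- cols_subset(b, b$from != b$to)
  # collapse duplicate bonds
  b <- m$bonds
  key <- paste(pmin(b$from, b$to), pmax(b$from, b$to))
  if (anyDuplicated(key)) {
    keep_rows <- logical(length(key))
    for (k in unique(key)) {
      rows <- which(key == k)
      exo <- bond_exoticness(m, rows)
      keep_rows[rows[which.max(exo)]] <- TRUE  # first of the maxima
    }
    m$bonds <- cols_subset(b, keep_rows)
  }
  remove_atoms(m, gone)
}

# Pick which of atoms i, j to retain: the more exotic, or the first (lower
# index) when equal.
pick_retained <- function(m, i, j) {
  ei <- atom_exoticness(m, i); ej <- atom_exoticness(m, j)
  if (ej > ei) c(j, i) else c(i, j)
}

#' Merge overlapping atoms between two partitions
#'
#' Examines pairwise combinations of atoms across the two groups (typically:
#' atoms from the starting structure vs. atoms from a grafted fragment); any
#' pair closer than `threshold` is merged — the more exotic atom is retained
#' (the first on a draw), the other's bonds are reassigned to it, and
#' duplicate bonds are collapsed keeping the more exotic bond. With both
#' groups empty, all atom pairs are eligible (the un-partitioned mode used by
#' primitives outside grafting).
#'
#' @param m A [molecule()].
#' @param group_a,group_b Disjoint atom index sets, or both empty for
#'   all-pairs mode.
#' @param threshold Overlap distance in Angstroms (default 0.2).
#' @return The merged molecule, carrying attributes `merged_count` (number of
#'   merge events) and `atom_map` (old index -> new index; atoms merged away
#'   map to the row of the atom that absorbed them).
#' @export
merge_overlapping <- function(m, group_a = integer(), group_b = integer(),
                              threshold = 0.2) {
  group_a <- as.integer(group_a); group_b <- as.integer(group_b)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  all_pairs <- !length(group_a) && !length(group_b)
  total_map <- seq_len(n_atoms(m))
  merged <- 0L
  repeat {
    n <- n_atoms(m)
    if (n < 2) break
    # candidate cross pairs, ascending distance
    if (all_pairs) {
      cand <- t(utils::combn(n, 2))
    } else {
      if (!length(group_a) || !length(group_b)) break
      cand <- as.matrix(expand.grid(group_a, group_b))
    }
    d <- sqrt((m$atoms$x[cand[, 1]] - m$atoms$x[cand[, 2]])^2 +
              (m$atoms$y[cand[, 1]] - m$atoms$y[cand[, 2]])^2)
    hit <- which(d < threshold)
    if (!length(hit)) break
    pair <- cand[hit[which.min(d[hit])], ]
    rk <- pick_retained(m, min(pair), max(pair))
    m <- merge_pair(m, rk[1], rk[2])
    merged <- merged + 1L
    map <- attr(m, "atom_map")
    map[rk[2]] <- map[rk[1]]  # merged-away atom now lives at the retained row
    total_map <- ifelse(is.na(total_map), NA_integer_, map[total_map])
    group_a <- unique(map[group_a[!is.na(map[group_a])]])
    group_b <- unique(map[group_b[!is.na(map[group_b])]])
    group_b <- setdiff(group_b, group_a)
  }
  attr(m, "merged_count") <- merged
  attr(m, "atom_map") <- total_map
  m
}
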