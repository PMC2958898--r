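# Template creation, grafting modes, scoring, ranking.

test_that("template excision converts boundary atoms to guides", {
  benz <- generate_fixture("benzene")
  t1 <- create_template(sketch_state(benz, selection = 1:6))
  expect_equal(n_atoms(t1$fragment), 6)
  expect_length(t1$guides, 0)

  # OMe on a ring: substructure plus one guide at the attachment carbon
  anis <- add_bond(add_atom(benz, "O", 0, 3), 1, 7)
  anis <- add_bond(add_atom(anis, "C", 1.3, 3.8), 7, 8)
  t2 <- create_template(sketch_state(anis, selection = c(7, 8)))
  expect_equal(n_atoms(t2$fragment), 3)
  expect_length(t2$guides, 1)
  expect_equal(t2$fragment$atoms$element[t2$guides], "*")
  expect_length(neighbours(t2$fragment, t2$guides), 1)

  # one atom of ethane: subject plus one guide
  eth <- chain_molecule(c("C", "C"))
  t3 <- create_template(sketch_state(eth, selection = 1))
  expect_equal(n_atoms(t3$fragment), 2)
  expect_length(t3$guides, 1)

  expect_error(create_template(sketch_state(benz)), "empty subject")
})

test_that("free placement offers distinct 30/45-degree rotations, clear of content", {
  benz_t <- built_in_template("benzene")
  out <- graft_no_connection(generate_fixture("benzene"), benz_t)
  expect_equal(length(out), 16)  # |{30k} union {45k}|
  for (m in out) {
    expect_equal(n_atoms(m), 12)
    # placement gap: fragment entirely right of the input bounding box
    expect_gte(min(m$atoms$x[7:12]), max(m$atoms$x[1:6]) + 1.5 - 1e-9)
  }
  # benzene's symmetry dedups the rotations in the ranked list
  g <- graft(sketch_state(molecule()), benz_t)
  expect_lt(length(g), 16)
  expect_gt(length(g), 1)
})

test_that("atom connection generates direct overlays and bridges", {
  benz <- generate_fixture("benzene")
  out <- graft_atom_connection(benz, 1, built_in_template("acetyl"))
  sizes <- vapply(out, n_atoms, integer(1))
  expect_true(any(sizes == 8))  # direct: one merge
  expect_true(any(sizes == 9))  # bridge: no merge
  bridged <- out[[which(sizes == 9)[1]]]
  expect_equal(attr(bridged, "merged_count"), 0L)
  direct <- out[[which(sizes == 8)[1]]]
  expect_equal(attr(direct, "merged_count"), 1L)
})

test_that("bond connection fuses rings; input coordinates are retained", {
  benz <- generate_fixture("benzene")
  out <- graft_bond_connection(benz, c(1, 2), built_in_template("benzene"))
  sizes <- vapply(out, function(m) paste(n_atoms(m), n_bonds(m)), character(1))
  expect_true("10 11" %in% sizes)  # naphthalene
  nap <- out[[which(sizes == "10 11")[1]]]
  # the input ring keeps its exact coordinates
  expect_equal(nap$atoms$x[1:6], benz$atoms$x)
  expect_equal(nap$atoms$y[1:6], benz$atoms$y)

  # mismatched lengths: input geometry wins on the fused bond
  small <- as_template(ring_mol <- {
    r <- molecule(rep("C", 3),
                  x = cos(c(90, 210, 330) * pi / 180),
                  y = sin(c(90, 210, 330) * pi / 180))
    r <- add_bond(r, 1, 2); r <- add_bond(r, 2, 3); add_bond(r, 3, 1)
  })
  out2 <- graft_bond_connection(benz, c(1, 2), small)
  fused <- out2[[1]]
  expect_equal(atom_dist(fused, 1, 2), 1.5, tolerance = 1e-9)
})

test_that("multiple connection requires every subject atom to overlap", {
  hept <- run_script(list(list(action = "graft", template = "cycloheptane",
                               result = 1)))$molecule
  t <- built_in_template("cycloheptane")
  out <- graft_multi_connection(hept, c(1, 3), t)
  expect_gt(length(out), 0)
  sizes <- vapply(out, n_atoms, integer(1))
  expect_true(any(sizes == 12))  # the reflected fusion

  # incompatible spacing: rejected outright
  bad <- molecule(c("C", "C"), x = c(0, 5), y = 0)
  expect_length(graft_multi_connection(bad, c(1, 2), t), 0)

  # scaled-down template (bond 1.0 vs spacing for 1.5 rings): rejected
  small_ring <- molecule(rep("C", 3),
                         x = (1 / sqrt(3)) * cos(c(90, 210, 330) * pi / 180),
                         y = (1 / sqrt(3)) * sin(c(90, 210, 330) * pi / 180))
  small_ring <- add_bond(small_ring, 1, 2)
  small_ring <- add_bond(small_ring, 2, 3)
  small_ring <- add_bond(small_ring, 3, 1)
  tri <- built_in_template("cyclopropane")$fragment
  expect_length(graft_multi_connection(tri, c(1, 2), as_template(small_ring)), 0)
})

test_that("guide grafting preserves the guide's direction and distance", {
  # one guide atom, one neighbour, non-default 2.0 A bond distance
  frag <- molecule(c("*", "O", "C"), x = c(0, 2, 3.5), y = 0)
  frag <- add_bond(frag, 1, 2)
  frag <- add_bond(frag, 2, 3)
  t <- as_template(frag)
  m <- chain_molecule(c("C", "C"))
  out <- graft_with_guides(m, 2, t)
  expect_gt(length(out), 0)
  r <- out[[1]]
  expect_false(any(r$atoms$element == "*"))
  expect_equal(attr(r, "guide_count"), 1L)
  # the guide bond was rewired to the subject at the guide's own distance
  o <- which(r$atoms$element == "O")
  expect_false(is.na(bond_between(r, 2, o)))
  expect_equal(atom_dist(r, 2, o), 2, tolerance = 1e-9)

  # two guides onto two subject atoms: guides deleted, fragment fused
  frag2 <- molecule(c("*", "*", "N"), x = c(0, 1.5, 0.75), y = c(0, 0, 1.3))
  frag2 <- add_bond(frag2, 1, 3)
  frag2 <- add_bond(frag2, 2, 3)
  t2 <- as_template(frag2)
  base <- molecule(c("C", "C"), x = c(0, 1.5), y = 0)
  out2 <- graft_with_guides(base, c(1, 2), t2)
  expect_gt(length(out2), 0)
  r2 <- out2[[1]]
  expect_equal(n_atoms(r2), 3)
  expect_false(any(r2$atoms$element == "*"))
  nn <- which(r2$atoms$element == "N")
  expect_false(is.na(bond_between(r2, 1, nn)))
  expect_false(is.na(bond_between(r2, 2, nn)))
  expect_equal(attr(r2, "guide_count"), 2L)
})

test_that("scores add congestion, merges, angle and valence penalties, guide credit", {
  m <- generate_fixture("benzene")
  expect_equal(score_graft_result(m), total_congestion(m))
  expect_equal(score_graft_result(m, merged_count = 3), total_congestion(m) + 3)
  expect_equal(score_graft_result(m, guide_count = 2), total_congestion(m) - 2)

  # pentavalent carbon: +1000 versus the identical tetravalent layout
  pent <- star_molecule(bearings = c(0, 72, 144, 216, 288))
  tet <- star_molecule(bearings = c(0, 90, 180, 270))
  expect_equal(score_graft_result(pent) - total_congestion(pent), 1000)
  expect_equal(score_graft_result(tet) - total_congestion(tet), 0)

  # sp3 carbon with a new bond at 100 degrees: +50; at 120 it is clean
  irregular <- star_molecule(bearings = c(0, 100))
  expect_equal(score_graft_result(irregular, new_bonds = 2L) -
                 total_congestion(irregular), 50)
  clean <- star_molecule(bearings = c(0, 120))
  expect_equal(score_graft_result(clean, new_bonds = 2L) -
                 total_congestion(clean), 0)
  # 118 degrees is inside the 5-degree tolerance
  near <- star_molecule(bearings = c(0, 118))
  expect_equal(score_graft_result(near, new_bonds = 2L) -
                 total_congestion(near), 0)

  # the closed form, recomputed term by term on a grafted candidate
  benz <- generate_fixture("benzene")
  cands <- graft_atom_connection(benz, 1, built_in_template("acetyl"))
  for (cand in cands[1:5]) {
    expect_equal(
      score_graft_result(cand, attr(cand, "merged_count"),
                         attr(cand, "guide_count"), attr(cand, "new_bonds")),
      brute_total_congestion(cand) + attr(cand, "merged_count") -
        attr(cand, "guide_count") +
        50 * local({
          nb <- attr(cand, "new_bonds")
          hits <- 0
          for (i in seq_len(n_atoms(cand))) {
            inc <- which(cand$bonds$from == i | cand$bonds$to == i)
            if (!length(inc)) next
            if (!cand$atoms$element[i] %in% c("C", "N", "O", "P", "S")) next
            if (cand$atoms$charge[i] != 0 || cand$atoms$unpaired[i] != 0) next
            ords <- cand$bonds$order[inc]
            hyb <- if (sum(ords == 3) == 1 || sum(ords == 2) == 2) 180
              else if (sum(ords == 2) == 1) 120
              else if (all(ords == 1)) 120 else NA
            if (is.na(hyb)) next
            newi <- intersect(inc, nb); oldi <- setdiff(inc, nb)
            if (!length(newi) || !length(oldi)) next
            bad <- FALSE
            for (kn in newi) for (ko in oldi) {
              jn <- setdiff(c(cand$bonds$from[kn], cand$bonds$to[kn]), i)
              jo <- setdiff(c(cand$bonds$from[ko], cand$bonds$to[ko]), i)
              v1 <- atan2(cand$atoms$y[jn] - cand$atoms$y[i],
                          cand$atoms$x[jn] - cand$atoms$x[i])
              v2 <- atan2(cand$atoms$y[jo] - cand$atoms$y[i],
                          cand$atoms$x[jo] - cand$atoms$x[i])
              sep <- abs(((v1 - v2) * 180 / pi + 180) %% 360 - 180)
              if (abs(sep - hyb) > 5) bad <- TRUE
            }
            if (bad) hits <- hits + 1
          }
          hits
        }) +
        1000 * sum(vapply(seq_len(n_atoms(cand)), function(i) {
          cand$atoms$element[i] %in% c("C", "N") &&
            sum(cand$bonds$order[cand$bonds$from == i | cand$bonds$to == i]) >= 5
        }, logical(1))),
      tolerance = 1e-9
    )
  }
})

test_that("ranking dedups, sorts ascending, and applies the 1000 cutoff", {
  fake <- function(score, mol) structure(
    list(molecule = mol, score = score, merged_count = 0L, guide_count = 0L,
         mode = "test"), class = "graft_result")
  a <- generate_fixture("benzene")
  b <- chain_molecule(c("C", "C"))
  out <- rank_and_filter(list(fake(2000, a), fake(3.1, b)))
  expect_equal(vapply(out, `[[`, numeric(1), "score"), 3.1)

  out2 <- rank_and_filter(list(fake(1500, a), fake(1200, b)))
  expect_equal(vapply(out2, `[[`, numeric(1), "score"), c(1200, 1500))

  out3 <- rank_and_filter(list(fake(5, a), fake(4, a), fake(6, b)))
  # the earliest of the two equivalent benzenes survives
  expect_equal(vapply(out3, `[[`, numeric(1), "score"), c(5, 6))
})

test_that("ranked graft output is clean: unique, sorted, no guides, no overlaps", {
  base <- generate_fixture("benzene")
  frag <- molecule(c("*", "O", "C"), x = c(0, 1.5, 3), y = 0)
  frag <- add_bond(frag, 1, 2)
  frag <- add_bond(frag, 2, 3)
  for (tpl in list(built_in_template("cyclopentane"), as_template(frag))) {
    res <- graft(sketch_state(base, current_atom = 1), tpl)
    expect_gt(length(res), 0)
    scores <- vapply(res, `[[`, numeric(1), "score")
    expect_true(all(diff(scores) >= -1e-12))
    for (i in seq_along(res)) {
      m <- res[[i]]$molecule
      expect_false(any(m$atoms$element == "*"))
      if (n_atoms(m) > 1)
        expect_gte(min(dist(cbind(m$atoms$x, m$atoms$y))), 0.2 - 1e-9)
      if (i > 1) expect_false(structures_equivalent(res[[1]]$molecule, m))
    }
  }
})

test_that("a mirror-symmetric template's candidates dedup to one per pose class", {
  # acetyl is mirror-symmetric about its carbonyl axis; direct grafts of the
  # template and its mirror coincide pairwise
  base <- molecule("C", 0, 0)
  res <- graft(sketch_state(base, current_atom = 1), built_in_template("acetyl"))
  mols <- lapply(res, `[[`, "molecule")
  for (i in seq_along(mols)) for (j in seq_along(mols)) {
    if (i < j) expect_false(structures_equivalent(mols[[i]], mols[[j]]))
  }
})
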