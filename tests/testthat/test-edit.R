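# Atom/bond property edits, connection, deletion, merging, movement.

test_that("adding atoms places them clear of existing content", {
  s <- add_atom_primitive(sketch_state(), "C")
  expect_equal(n_atoms(s$molecule), 1)
  expect_equal(c(s$molecule$atoms$x, s$molecule$atoms$y), c(0, 0))
  expect_equal(s$current_atom, 1L)

  s2 <- add_atom_primitive(sketch_state(generate_fixture("benzene")), "N")
  m <- s2$molecule
  expect_gt(m$atoms$x[7], max(m$atoms$x[1:6]) + 1)
  expect_gte(m$atoms$y[7], max(m$atoms$y[1:6]))

  s3 <- add_atom_primitive(s2, "O")
  d <- pairwise_dists(s3$molecule, 7:8)
  expect_gt(min(d), 0.2)
})

test_that("atom property edits hit every subject atom; empty subject adds", {
  m <- chain_molecule(c("C", "C", "C"))
  s <- sketch_state(m, selection = c(1, 3))
  s <- set_atom_property(s, "element", "O")
  expect_equal(s$molecule$atoms$element, c("O", "C", "O"))

  s2 <- set_atom_property(sketch_state(m, current_atom = 2), "charge", 1)
  expect_equal(s2$molecule$atoms$charge, c(0L, 1L, 0L))
  expect_equal(s2$molecule$atoms$element, c("C", "C", "C"))

  s3 <- set_atom_property(sketch_state(m), "element", "N")
  expect_equal(n_atoms(s3$molecule), 4)
  expect_equal(s3$molecule$atoms$element[4], "N")

  expect_error(set_atom_property(sketch_state(m, current_atom = 1), "unpaired", -1),
               ">= 0")
})

test_that("set bond order covers the delegation, creation and reset rules", {
  m <- chain_molecule(c("C", "C"))
  m$bonds$stereo <- "inclined"
  s <- sketch_state(m, current_bond = 1)
  s <- set_bond_order(s, 2)
  expect_equal(s$molecule$bonds$order, 2L)
  expect_equal(s$molecule$bonds$stereo, "none")  # stereo reset

  m2 <- molecule(c("C", "C"), x = c(0, 3), y = 0)
  s2 <- set_bond_order(sketch_state(m2, selection = c(1, 2)), 1)
  expect_equal(n_bonds(s2$molecule), 1)

  s3 <- set_bond_order(sketch_state(molecule("C", 0, 0), current_atom = 1), 1)
  expect_equal(n_atoms(s3$molecule), 2)  # delegated to new bond
  expect_equal(n_bonds(s3$molecule), 1)
})

test_that("stereo styling wedges bonds and reverses repeated wedges", {
  m <- chain_molecule(c("C", "C"))
  s <- sketch_state(m, current_bond = 1)
  s <- set_stereo_style(s, "inclined")
  expect_equal(s$molecule$bonds$stereo, "inclined")
  expect_equal(s$molecule$bonds$from, 1L)
  s <- set_stereo_style(s, "inclined")
  expect_equal(s$molecule$bonds$from, 2L)  # endpoints swapped
  expect_equal(s$molecule$bonds$to, 1L)

  s2 <- set_stereo_style(sketch_state(molecule("C", 0, 0), current_atom = 1), "declined")
  expect_equal(n_atoms(s2$molecule), 2)
  expect_equal(s2$molecule$bonds$stereo, "declined")
  expect_equal(s2$molecule$bonds$from, 1L)  # wedge emanates from the subject
})

test_that("connect joins near-default pairs, or only the closest pair", {
  m <- molecule(c("C", "C"), x = c(0, 1.5), y = 0)
  s <- connect_atoms(sketch_state(m, selection = c(1, 2)))
  expect_equal(n_bonds(s$molecule), 1)
  expect_equal(s$molecule$bonds$order, 1L)
  expect_equal(s$molecule$bonds$stereo, "none")

  # three collinear at 1.5 spacing: ends are 3.0 apart, not joined
  m2 <- molecule(rep("C", 3), x = c(0, 1.5, 3), y = 0)
  s2 <- connect_atoms(sketch_state(m2, selection = 1:3))
  expect_equal(n_bonds(s2$molecule), 2)
  expect_true(is.na(bond_between(s2$molecule, 1, 3)))

  # nothing near the default distance: closest pair only
  m3 <- molecule(rep("C", 3), x = c(0, 4, 9), y = 0)
  s3 <- connect_atoms(sketch_state(m3, selection = 1:3))
  expect_equal(n_bonds(s3$molecule), 1)
  expect_false(is.na(bond_between(s3$molecule, 1, 2)))

  expect_warning(connect_atoms(sketch_state(m, selection = 1)), "fewer than two")
})

test_that("disconnect and delete touch exactly the subject", {
  m <- chain_molecule(rep("C", 3))
  s <- disconnect_atoms(sketch_state(m, current_bond = 1))
  expect_equal(n_atoms(s$molecule), 3)
  expect_equal(n_bonds(s$molecule), 1)

  # ethane: delete one atom removes its bond too
  e <- chain_molecule(c("C", "C"))
  s2 <- delete_subject(sketch_state(e, selection = 1), "atoms")
  expect_equal(n_atoms(s2$molecule), 1)
  expect_equal(n_bonds(s2$molecule), 0)

  # bonds mode leaves atoms and their fields untouched
  e2 <- chain_molecule(c("N", "C"))
  e2$atoms$charge[1] <- 1L
  s3 <- delete_subject(sketch_state(e2, selection = c(1, 2)), "bonds")
  expect_equal(n_atoms(s3$molecule), 2)
  expect_equal(n_bonds(s3$molecule), 0)
  expect_equal(s3$molecule$atoms$charge[1], 1L)

  s4 <- delete_subject(sketch_state(e2, selection = 1), "all")
  expect_equal(n_atoms(s4$molecule), 0)

  # intra-ring disconnect of one naphthalene ring
  naph <- run_script(list(list(action = "graft", template = "naphthalene",
                               result = 1)))$molecule
  ring <- component_ring <- 1:6  # first six atoms form one ring in the fixture
  nb_before <- n_bonds(naph)
  s5 <- disconnect_atoms(sketch_state(naph, selection = ring))
  removed <- nb_before - n_bonds(s5$molecule)
  expect_equal(removed, sum(naph$bonds$from %in% ring & naph$bonds$to %in% ring))
})

test_that("merge atoms averages positions and keeps the exotic atom", {
  m <- molecule(c("C", "C"), x = c(0, 0.3), y = 0)
  s <- merge_atoms(sketch_state(m, selection = 1))
  expect_equal(n_atoms(s$molecule), 1)
  expect_equal(s$molecule$atoms$x, 0.15)

  m2 <- molecule(c("C", "O"), x = c(0, 0.3), y = 0)
  s2 <- merge_atoms(sketch_state(m2, selection = 1))
  expect_equal(s2$molecule$atoms$element, "O")

  m3 <- molecule(c("C", "C"), x = c(0, 1.4), y = 0)
  s3 <- merge_atoms(sketch_state(m3, selection = 1))
  expect_equal(n_atoms(s3$molecule), 2)  # outside tolerance: no-op
})

test_that("movement primitives translate by nudges or past the others", {
  m <- molecule(rep("C", 3), x = c(0, 1, 4), y = c(0, 2, 0))
  s <- move_atoms(sketch_state(m, selection = c(1, 2)), "right", "small_nudge")
  expect_equal(s$molecule$atoms$x, c(0.1, 1.1, 4))
  expect_equal(s$molecule$atoms$y, c(0, 2, 0))
  s <- move_atoms(s, "down", "large_nudge")
  expect_equal(s$molecule$atoms$y, c(-0.5, 1.5, 0))

  # furthest right: subject min x ends 1 beyond non-subject max x
  s2 <- move_atoms(sketch_state(m, selection = c(1, 2)), "right", "furthest")
  expect_equal(min(s2$molecule$atoms$x[1:2]), 5)
  expect_equal(diff(s2$molecule$atoms$x[1:2]), 1)  # rigid

  # whole molecule selected: no other atoms, no movement
  s3 <- move_atoms(sketch_state(m, selection = 1:3), "left", "furthest")
  expect_equal(s3$molecule$atoms$x, m$atoms$x)
})

test_that("scaling atoms is a similarity about the right centre", {
  m <- molecule(c("C", "C"), x = c(0, 1), y = 0)
  s <- scale_atoms(sketch_state(m, selection = c(1, 2)), "grow")
  expect_equal(pairwise_dists(s$molecule), 1.25)

  s2 <- scale_atoms(s, "shrink")
  expect_equal(pairwise_dists(s2$molecule), 1, tolerance = 1e-9)
  expect_equal(s2$molecule$atoms$x, m$atoms$x, tolerance = 1e-9)

  # a current atom supplies the fixed point
  m3 <- molecule(rep("C", 3), x = c(0, 1, 2), y = 0)
  s3 <- sketch_state(m3, selection = c(2, 3), current_atom = 1)
  s3$selection <- c(2L, 3L)
  r <- scale_atoms(s3, "grow")
  expect_equal(r$molecule$atoms$x, c(0, 1.25, 2.5))
})

test_that("bond scaling moves the lighter side, halves, or ring atoms only", {
  # unequal sides: the smaller side's whole branch translates
  m <- chain_molecule(rep("C", 5))          # 1-2-3-4-5, scale bond 3-4
  s <- scale_bond(sketch_state(m, current_bond = bond_between(m, 3, 4)), "grow")
  r <- s$molecule
  expect_equal(atom_dist(r, 3, 4), 1.875)
  expect_equal(r$atoms$x[1:3], m$atoms$x[1:3])          # big side fixed
  expect_equal(atom_dist(r, 4, 5), 1.5)                 # branch rigid

  # equal sides move half each
  m2 <- chain_molecule(rep("C", 4))
  s2 <- scale_bond(sketch_state(m2, current_bond = bond_between(m2, 2, 3)), "grow")
  r2 <- s2$molecule
  expect_equal(atom_dist(r2, 2, 3), 1.875)
  expect_equal(r2$atoms$x[2] - m2$atoms$x[2], -(r2$atoms$x[3] - m2$atoms$x[3]))

  # ring bond: only the two bonded atoms move
  benz <- generate_fixture("benzene")
  s3 <- scale_bond(sketch_state(benz, current_bond = 1), "grow")
  r3 <- s3$molecule
  expect_equal(atom_dist(r3, 1, 2), 1.875, tolerance = 1e-9)
  expect_equal(r3$atoms$x[3:6], benz$atoms$x[3:6])
})

test_that("flips reflect about the subject centre and are involutions", {
  m <- molecule(rep("C", 3), x = c(0, 1, 2), y = c(0, 1, 0))
  s <- flip_atoms(sketch_state(m, selection = 1:3), "vertical")
  cy <- mean(m$atoms$y)
  expect_equal(s$molecule$atoms$y, 2 * cy - m$atoms$y)
  expect_equal(s$molecule$atoms$x, m$atoms$x)

  s2 <- flip_atoms(s, "vertical")
  expect_equal(s2$molecule$atoms$y, m$atoms$y, tolerance = 1e-9)

  # current atom only: whole connected component flips about it
  two <- chain_molecule(c("C", "C"))
  f <- flip_atoms(sketch_state(two, current_atom = 1), "horizontal")
  expect_equal(f$molecule$atoms$x, c(0, -1.5))
})

test_that("rotation is rigid and honours the terminal-bond special case", {
  m <- chain_molecule(c("C", "C", "C"))
  m <- add_bond(add_atom(m, "C", 1.5, 1.5), 2, 4)
  # current bond 2-1 with 1 terminal: 1 orbits 2
  s <- rotate_atoms(sketch_state(m, current_bond = bond_between(m, 1, 2)), 30)
  r <- s$molecule
  expect_equal(atom_dist(r, 1, 2), 1.5, tolerance = 1e-9)
  expect_equal(r$atoms$x[2:4], m$atoms$x[2:4])
  ang <- (atan2(r$atoms$y[1] - r$atoms$y[2], r$atoms$x[1] - r$atoms$x[2]) -
          atan2(m$atoms$y[1] - m$atoms$y[2], m$atoms$x[1] - m$atoms$x[2])) * 180 / pi
  expect_equal((ang + 360) %% 360, 30, tolerance = 1e-9)

  # +15 then -15 restores the coordinates
  tri <- molecule(rep("C", 3), x = c(0, 2, 1), y = c(0, 0, 2))
  s2 <- rotate_atoms(sketch_state(tri, selection = 1:3), 15)
  s2 <- rotate_atoms(s2, -15)
  expect_equal(s2$molecule$atoms$x, tri$atoms$x, tolerance = 1e-9)
  expect_equal(s2$molecule$atoms$y, tri$atoms$y, tolerance = 1e-9)

  # rigid: pairwise distances preserved
  s3 <- rotate_atoms(sketch_state(tri, selection = 1:3), 30)
  expect_equal(pairwise_dists(s3$molecule), pairwise_dists(tri), tolerance = 1e-9)
})
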