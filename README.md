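# sketchmol

A headless engine for sketching 2D molecular structure diagrams with
discrete editing primitives — no mouse, no GUI, no pixel coordinates from
the user. It is written for the situation where input bandwidth is scarce
(scripted pipelines, constrained devices, server round-trips): every edit
is a *subject → action → result* step, and the engine infers all geometry
itself, so a publication-quality connection table is just the replay of a
short script.

The core ideas:

* **Geometry perception.** An atom's existing bond bearings are matched
  (within 2°, rotations and mirror included) against seven idealized
  geometry templates — linear, trigonal, two tetrahedral variants, square
  planar, two octahedral variants — chosen from its element, valence and
  the order of the incoming bond. The unoccupied template slots are the
  candidate directions for a new bond; irregular atoms fall back to the
  circular midpoints between existing bearings.
* **Congestion.** Degenerate choices are resolved by the congestion
  function `sum_i 1 / (d_i² + 0.001)` (distances in Å): new atoms and
  grafted fragments go where the drawing is emptiest.
* **Template grafting.** Fragments fuse onto the sketch by atom overlay,
  bond alignment, bridging bonds, or `*` guide atoms that carry a preferred
  attachment direction and distance. Candidates are deduplicated by a
  coordinate-level sketch-equivalence test, scored (congestion, +1 per
  merged atom, +50 per irregular bond angle at a clearly hybridised
  C/N/O/P/S atom, +1000 per pentavalent C/N, −1 per guide) and ranked.
* **Connection tables.** Molecules are ordered atom/bond tables with
  charges, radicals, isotopes, explicit hydrogens and wedge stereo, read
  and written as MDL molfile V2000 and multi-record SD files.

## A worked example

Draw toluene from nothing: graft a benzene template onto the empty canvas,
make ring atom 1 current, and grow one single bond.

```r
library(sketchmol)

s <- sketch_state()
g <- graft(s, built_in_template("benzene"))   # 8 distinct rotations, ranked
s <- sketch_state(g[[1]]$molecule)            # take the best-scoring one
s <- set_current_atom(s, 1)
s <- new_bond_with_order(s, 1)
print(s)
#> molecule: 7 atoms, 7 bonds
#>   atoms: C7
#>   current atom: 7
```

The new carbon lands on the exocyclic trigonal vacancy, 1.5 Å from its
anchor and pointing away from the ring (the least congested of the inferred
directions), as the written molfile shows — atom 7 sits at (0.0, 3.0),
directly above ring atom 1 at (0.0, 1.5):

```
  7  7  0  0  0  0  0  0  0  0999 V2000
    0.0000    1.5000    0.0000 C   ...
    ...
    0.0000    3.0000    0.0000 C   ...
```

Grafts return a ranked list you can inspect before committing:

```r
res <- graft(sketch_state(generate_fixture("benzene"), current_atom = 1),
             built_in_template("acetyl"))
res[[1]]
#> graft result (atom_connection): score 6.5066, 0 merged, 0 guides
#> molecule: 9 atoms, 9 bonds
```

Whole drawings are JSON scripts. The package ships the three worked
examples — aspirin (9 steps), the ingenol skeleton, and a gold catalytic
intermediate — with hand-transcribed reference connection tables:

```r
s <- run_script(example_script("aspirin"))
isomorphic_sketch(s$molecule, generate_fixture("aspirin"))
#> [1] TRUE
```

A thin command-line wrapper is installed with the package
(`system.file("cli", "sketch", package = "sketchmol")`):

```sh
sketch apply --script aspirin.json --out aspirin.mol
sketch graft --template acetyl --in aspirin.mol --subject 10 --show-ranked
sketch equiv a.mol b.mol
sketch templates list
```

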