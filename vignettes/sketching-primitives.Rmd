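---
title: "Sketching molecular diagrams with discrete primitives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketching molecular diagrams with discrete primitives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sketchmol)
```

## The editing model

sketchmol builds 2D molecular connection tables without a pointing device.
Every edit is a *primitive*: a discrete operation that takes a **subject**
(the current atom, the current bond, or a set of selected atoms), an
**action**, and — for actions with several plausible outcomes — a **result**
index into a ranked candidate list. Because no primitive consumes pointer
coordinates, a whole drawing is a short replayable script of such steps, and
the engine must infer all geometry itself.

The *subject atoms* of a primitive are the selected atoms if any exist,
otherwise the current atom, otherwise the two atoms of the current bond,
otherwise nothing. Selected atoms are taken in ascending index order; the
grafting modes that speak of the "first subject atom" rely on this ordering,
since a replay script cannot observe the order in which a user clicked.

Coordinates are in Angstroms; the default distance between bonded atoms is
1.5 Å regardless of elements or bond order, and two atoms closer than 0.2 Å
are considered overlapping — a cue for merging in some primitives and an
error state otherwise.

## Geometry perception

The engine anticipates where the next bond belongs by matching an atom's
existing bond bearings against seven idealized **geometry templates**:

```{r}
geometry_template()
```

Each template is a set of bond directions defined up to a common rotation.
The two tetrahedral variants are the familiar 120/60/60/120 and
60/120/60/120 wedge layouts; `octa1` is the regular hexagonal star and
`octa2` extends square planar by the two 45° diagonals, which makes the
octahedral pair a superset of most of the other templates and therefore the
fallback for transition metals. These exact angle sets are a design choice
of this package (the layouts are conventional but not uniquely determined);
they are isolated in one table so they could be revised without touching any
algorithm.

Which templates are worth trying is decided from the element, the existing
bond orders and the order of the incoming bond: a terminal carbon or
nitrogen heading for an alkyne- or allene-like pattern (order multiset
{1,3} or {2,2}) is linear; terminal atoms outside the s- and p-blocks get
the octahedral pair; carbon with all-single bonds may be trigonal, square
planar or tetrahedral; p-block elements of periods 2–4 get the tetrahedral
set, heavier p-block anything, and everything else the octahedral pair.

A template *matches* when some rotation of it (or of its mirror image —
mirroring is stated for geometry refitting and enabled everywhere for
consistency) superimposes every existing bearing on a distinct slot within
**2°**. Matching is seeded at every (bearing, slot) pair rather than solved
as a continuous optimisation; with a 2° window the seeds cover every
attainable rotation. The unoccupied slots are the *vacancies* — the
candidate directions for a new bond; vacancies duplicated across rotations
are collapsed at the same 2° tolerance. An isolated atom proposes the four
axis directions; an atom whose bearings match no plausible template falls
back to *median-cut* angles, the circular midpoints between consecutive
bearings (this covers both irregular layouts and full valences).

Among candidate directions, ties are resolved by **congestion**: the sum
over atoms of `1 / (d² + 0.001)` at the probed point (and over unique atom
pairs for a whole molecule). The additive 0.001 Å² softening constant keeps
the value finite at zero distance (a point on top of an atom scores exactly
1000). The least congested candidate wins; exact ties break toward the
smallest angle — an arbitrary but deterministic convention.

`set_geometry()` refits non-matching atoms: every pairing of an existing
bond with a template slot (template and mirror) seeds a rotation, remaining
bonds snap to the nearest distinct slots, and the assignment with the
smallest total angular displacement wins, ties preferring the non-mirrored
template and then the lowest seed slot. Bonds inside rings must not move —
an assignment that would rotate one is discarded, and if all are discarded
the refit fails. A moved neighbour carries its entire acyclic branch
rigidly, so substituent internal geometry is preserved exactly.

`switch_geometry()` re-estimates the geometry of a terminal bond's anchor
*as if the bond were absent*, then rotates the bond (length preserved) to
the nearest vacancy anti-clockwise; repeated use cycles through all
positions, which is the escape hatch when the congestion heuristic guesses
a legal but unintended direction.

## Merging and exoticness

When two atoms come to occupy the same position (within 0.2 Å), one must
absorb the other. The survivor is the more *exotic* atom — one point each
for a non-carbon label, non-zero charge, unpaired electrons, a non-default
isotope and an explicit hydrogen count — with the earlier index winning a
draw; the absorbed atom's bonds are rewired to it and duplicate bonds
collapse the same way (one point each for order ≠ 1 and any stereo
assignment). Grafting partitions atoms by origin (input vs. fragment) and
merges only across the partition; the `merge_atoms()` primitive uses the
same rules un-partitioned with a deliberately looser 0.5 Å capture radius —
a third of the default bond distance, chosen so that atoms dragged roughly
together snap cleanly while ordinary bonded neighbours never do — and
moves the survivor to the cluster average.

Two other free constants were fixed the same way: `connect_atoms()` treats
"approximately the default bond distance" as 1.5 ± 0.3 Å (20%), and the
move nudges are exactly 0.1 and 0.5 Å.

## Grafting

A template is a molecule fragment, possibly with `"*"` guide atoms marking
where and how it expects to be attached. `create_template()` excises the
subject substructure; boundary neighbours become guides. Grafting dispatches
on the subject and the guides:

* no subject — the fragment is placed to the right of the existing content
  (vertically centred, 1.5 Å gap) in every distinct rotation by multiples
  of 30° and 45°;
* one subject atom — for each fragment atom, template and mirror: *direct*
  overlay (atoms merged) and *bridge* (new single bond), over all pairs of
  projected angles from both sides, rotated by θ₁−θ₂+180°;
* a subject bond — fragment bonds aligned parallel and anti-parallel on it,
  matched atoms merged with the input coordinates retained;
* several subject atoms — the first two subjects anchor a rigid placement;
  every remaining subject must overlap a fragment atom or the pose is
  rejected (no rescaling is attempted);
* guides present — the guide configuration picks constrained variants of
  the above: a single-neighbour guide transfers its own direction and bond
  length (this is how non-default geometries survive grafting); a
  multi-neighbour guide contributes the circular mean of its bond
  directions; k guides map onto k subjects. Guides are deleted afterwards
  and their bonds rewired to the subjects.

For the multi-neighbour-guide case (the chelating-ligand pattern: the
guide marks a metal position surrounded by donor atoms) the design question
is which way the ligand's composite direction should face relative to the
subject's projected bond angle. We align the guide's median direction onto
the projection angle with the guide superimposed on the subject atom, so
the ligand spreads *into* the open coordination site — the orientation
that closes a chelate rather than folding it back over the existing
substituents.

Every candidate is scored, lower is better: total congestion, +1 per
positional merge, +50 per clearly sp/sp²/sp³ C, N, O, P or S atom whose new
bond sits more than 5° from the ideal 120° (sp³/sp²) or 180° (sp) relative
to a pre-existing neighbour, +1000 per carbon or nitrogen with total bond
order ≥ 5, and −1 per guide consumed. "Clearly hybridised" is decided from
the drawn bond orders alone (one triple or two doubles → sp; exactly one
double → sp²; all single with a neighbour → sp³), and "new bond" means
absent from the pre-graft structure, tracked through the merge maps.
Candidates that are equivalent as sketches are deduplicated (earliest
generation order wins), the rest sorted by score, and — when the best score
is under 1000 — any candidate at 1000 or more is dropped as structurally
absurd.

## Sketch equivalence

Two sketches are the same drawing (not merely the same molecule) when their
atom and bond counts agree, their atoms map one-to-one within 0.2 Å after
centring, mapped atoms agree in every field, and every bond has a
counterpart of equal order and stereo — directionally for wedges, whose
narrow end is significant. The positional mapping is greedy
nearest-neighbour with uniqueness, in ascending distance order; with the
0.2 Å window on 1.5 Å bond lengths the greedy map and the optimal
assignment coincide in practice. Kekulé forms and tautomers compare as
different, deliberately — this is a test for redundant depictions, not a
canonical identifier like unique SMILES or InChI.

## Scripts and the worked examples

A script is a JSON list of steps, each optionally resetting the subject and
applying one action (`run_script()`). Subject indices refer to the evolving
molecule's atom order; deletions and merges renumber atoms, so scripts must
be written against the engine's deterministic numbering — the cost of
replacing interactive selection with replayable text.

The package ships three example scripts (`example_script()`) that draw
aspirin, the ingenol skeleton and a gold catalytic intermediate from
scratch, and `generate_fixture()` returns hand-encoded reference
connection tables for them. The fixtures are transcriptions: the action
sequences follow the classic demonstration drawings for these three
molecules step for step (including the deliberately repeated steps), while
the subject chosen at each step — which ring atom to grow from, which bond
to fuse across — was fixed here so that the sequence reproduces the target
structure's graph. The replay tests therefore demonstrate that the full
primitive alphabet composes end-to-end (free grafting, multi-atom fusion,
bond fusion, deletion, clipboard copy/paste through a guide atom,
geometry-template bonds, wedges, relabels) and that every engine-created
bond comes out at exactly 1.5 Å; equivalence to any one hand drawing of
the same molecules, coordinate for coordinate, is not claimed.

```{r}
s <- run_script(example_script("aspirin"))
s$molecule
isomorphic_sketch(s$molecule, generate_fixture("aspirin"))
```

## Numerical choices and limitations

All tolerances live in one place: 2° for geometry matching and vacancy
degeneracy, 5° for the scoring angle window, 0.2 Å for overlap and
equivalence, 0.5 Å for merge capture, ±0.3 Å for connect. Angles are
degrees, counter-clockwise, 0° along +x, y up; positive rotations are
anti-clockwise. Flips do not exchange inclined and declined wedges (the
exchange is specified only for template mirroring); if a flip is used
across a stereocentre the depicted chirality therefore inverts, a
documented caveat isolated in `flip_atoms()`.

Everything is deterministic: identical scripts and inputs produce
bit-identical molfiles, which the test suite asserts. The problem sizes
exercised throughout — molecules up to ~40 atoms, candidate lists up to a
few hundred before deduplication — are the sizes this editing model is for;
all example replays and the full property suite run in seconds on one CPU.

Out of scope: automatic full-molecule layout from topology alone,
beautification after each step, aromatic (type 4) bond semantics, query
features, S-groups, 3D coordinates, and canonical identifiers. The V3000
molfile dialect is not read or written; V2000 covers the 999-atom range far
beyond this editing model's intent.
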