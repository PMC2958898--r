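# Reference connection tables for the worked drawing examples, transcribed
# by hand (elements, bonds, orders; schematic coordinates). Replays of the
# example scripts are checked against these by element- and order-labelled
# graph isomorphism, so only the topology and labels are authoritative here.

# Compact builder: elements as a vector, bonds as a list of c(from, to, order).
.fixture <- function(elements, bonds) {
  m <- molecule(elements, x = seq_along(elements) * 1.5, y = 0)
  for (b in bonds) m <- add_bond(m, b[1], b[2], b[3])
  m
}

.aspirin_fixture <- function() {
  # acetylsalicylic acid: benzene ring (1-6), carboxyl (7, =O 8, OH 9),
  # ester oxygen (10), acetyl (11, =O 12, methyl 13)
  .fixture(
    c("C", "C", "C", "C", "C", "C", "C", "O", "O", "O", "C", "O", "C"),
    list(c(1, 2, 2), c(2, 3, 1), c(3, 4, 2), c(4, 5, 1), c(5, 6, 2), c(6, 1, 1),
         c(1, 7, 1), c(7, 8, 2), c(7, 9, 1),
         c(2, 10, 1), c(10, 11, 1), c(11, 12, 2), c(11, 13, 1))
  )
}

.ingenol_fixture <- function() {
  # ingenol skeleton: bicyclo[4.4.1]undecane (1-11; one-carbon bridge 12-ish
  # position is atom 2), cyclopentane fused on bond 4-5 (12-14), cyclopropane
  # on bond 9-10 (15), exocyclic methylene (16), ring alkene 6=7, methyl
  # (17), stereo substituents (18, 19 -> explicit H), gem-dimethyl on the
  # cyclopropane apex (20, 21), hydroxyl (22)
  .fixture(
    c(rep("C", 15), "C", "C", "C", "H", "C", "C", "O"),
    list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 5, 1), c(5, 6, 1),
         c(6, 7, 2), c(7, 1, 1),
         c(1, 8, 1), c(8, 9, 1), c(9, 10, 1), c(10, 11, 1), c(11, 3, 1),
         c(4, 12, 1), c(12, 13, 1), c(13, 14, 1), c(14, 5, 1),
         c(10, 15, 1), c(15, 9, 1),
         c(13, 16, 2),
         c(8, 17, 1),
         c(11, 18, 1), c(12, 19, 1),
         c(15, 20, 1), c(15, 21, 1),
         c(14, 22, 1))
  )
}

.gold_fixture <- function() {
  # gold catalytic intermediate: linear two-coordinate Au(1) bearing a
  # three-ring diaminocarbene (2-4) with a diisopropylated aryl arm on N4
  # (6-17) and its copy pasted onto the N3 methylene C5 (18-29), and a
  # carboxylate chain Au-O30-C31(=O32) capped by a five-ring (33-37) with
  # N/O relabels
  .fixture(
    c("Au", "C", "N", "N", "C",
      "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C",
      "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C",
      "O", "C", "O",
      "C", "N", "O", "C", "C"),
    list(c(1, 2, 2),
         c(2, 3, 1), c(3, 4, 1), c(4, 2, 1),
         c(3, 5, 1),
         c(4, 6, 1),
         c(6, 7, 2), c(7, 8, 1), c(8, 9, 2), c(9, 10, 1), c(10, 11, 2), c(11, 6, 1),
         c(7, 12, 1), c(11, 13, 1),
         c(12, 14, 1), c(13, 15, 1), c(12, 16, 1), c(13, 17, 1),
         c(5, 18, 1),
         c(18, 19, 2), c(19, 20, 1), c(20, 21, 2), c(21, 22, 1), c(22, 23, 2),
         c(23, 18, 1),
         c(19, 24, 1), c(23, 25, 1),
         c(24, 26, 1), c(25, 27, 1), c(24, 28, 1), c(25, 29, 1),
         c(1, 30, 1), c(30, 31, 1), c(31, 32, 2),
         c(31, 33, 1),
         c(33, 34, 2), c(34, 35, 1), c(35, 36, 2), c(36, 37, 1), c(37, 33, 1))
  )
}

#' Reference connection tables for the worked examples
#'
#' Hand-encoded reference structures (elements, bonds, orders, schematic
#' coordinates) against which replays of the shipped drawing scripts are
#' compared by [isomorphic_sketch()].
#'
#' @param name One of `aspirin`, `ingenol`, `gold_intermediate`, `benzene`,
#'   or `ring3` .. `ring8`.
#' @return A [molecule()].
#' @export
generate_fixture <- function(name) {
  if (grepl("^ring[3-8]$", name)) {
    return(ring_molecule(as.integer(sub("ring", "", name))))
  }
  switch(name,
    benzene = benzene_molecule(),
    aspirin = .aspirin_fixture(),
    ingenol = .ingenol_fixture(),
    gold_intermediate = .gold_fixture(),
    stop("unknown fixture: ", name)
  )
}

#' Shipped drawing scripts for the worked examples
#'
#' Returns the path to one of the JSON primitive scripts installed with the
#' package, for replay with [run_script()].
#'
#' @param name One of `aspirin`, `ingenol`, `gold_intermediate`.
#' @return File path.
#' @export
example_script <- function(name) {
  name <- match.arg(name, c("aspirin", "ingenol", "gold_intermediate"))
  f <- system.file("scripts", paste0(name, ".json"), package = "sketchmol")
  if (!nzchar(f)) stop("script not found: ", name)
  f
}
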