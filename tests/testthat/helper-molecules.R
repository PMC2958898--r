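# Builders and independent oracles shared across the suite.

# chain/star helpers -------------------------------------------------------

chain_molecule <- function(elements, spacing = 1.5) {
  m <- molecule(elements, x = (seq_along(elements) - 1) * spacing, y = 0)
  for (i in seq_len(length(elements) - 1)) m <- add_bond(m, i, i + 1)
  m
}

# atom at origin plus neighbours at given bearings (degrees) and distance
star_molecule <- function(centre = "C", bearings = numeric(), dist = 1.5,
                          orders = rep(1L, length(bearings))) {
  m <- molecule(c(centre, rep("C", length(bearings))),
                x = c(0, dist * cos(bearings * pi / 180)),
                y = c(0, dist * sin(bearings * pi / 180)))
  for (k in seq_along(bearings)) m <- add_bond(m, 1, k + 1, orders[k])
  m
}

# random small molecule with exotic properties, for round-trip/equivalence
# properties (no overlapping atoms; random tree plus extra edges)
random_molecule <- function(n, seed) {
  set.seed(seed)
  repeat {
    x <- round(runif(n, -6, 6), 4)
    y <- round(runif(n, -6, 6), 4)
    if (n < 2 || min(dist(cbind(x, y))) > 0.45) break
  }
  els <- sample(c("C", "C", "C", "N", "O", "S", "Fe", "Cl"), n, replace = TRUE)
  m <- molecule(els, x = x, y = y)
  m$atoms$charge <- sample(c(0L, 0L, 0L, -1L, 1L), n, replace = TRUE)
  m$atoms$unpaired <- sample(c(0L, 0L, 0L, 1L), n, replace = TRUE)
  m$atoms$isotope <- ifelse(runif(n) < 0.2, 13L, NA_integer_)
  m$atoms$hydrogens <- ifelse(runif(n) < 0.2, sample(0:3, n, replace = TRUE),
                              NA_integer_)
  if (n >= 2) {
    for (i in 2:n) m <- add_bond(m, sample(i - 1, 1), i,
                                 sample(c(1L, 1L, 2L, 3L), 1),
                                 sample(c("none", "none", "inclined", "declined",
                                          "unknown"), 1))
  }
  m
}

# brute-force congestion oracles (term-by-term, independent of the package
# implementation)
brute_point_congestion <- function(m, x, y) {
  total <- 0
  for (i in seq_len(n_atoms(m))) {
    total <- total + 1 / ((m$atoms$x[i] - x)^2 + (m$atoms$y[i] - y)^2 + 0.001)
  }
  total
}

brute_total_congestion <- function(m) {
  total <- 0
  n <- n_atoms(m)
  if (n < 2) return(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + 1 / ((m$atoms$x[i] - m$atoms$x[j])^2 +
                          (m$atoms$y[i] - m$atoms$y[j])^2 + 0.001)
  }
  total
}

bond_lengths <- function(m) {
  sqrt((m$atoms$x[m$bonds$from] - m$atoms$x[m$bonds$to])^2 +
       (m$atoms$y[m$bonds$from] - m$atoms$y[m$bonds$to])^2)
}

pairwise_dists <- function(m, ids = seq_len(n_atoms(m))) {
  as.numeric(dist(cbind(m$atoms$x[ids], m$atoms$y[ids])))
}

# hand-written benzene V2000 block (independent of write_molfile)
BENZENE_V2000 <- paste(c(
  "benzene", "  test", "",
  "  6  6  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -1.2990    0.7500    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -1.2990   -0.7500    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.0000   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.2990   -0.7500    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.2990    0.7500    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  2  0  0  0  0",
  "  2  3  1  0  0  0  0",
  "  3  4  2  0  0  0  0",
  "  4  5  1  0  0  0  0",
  "  5  6  2  0  0  0  0",
  "  6  1  1  0  0  0  0",
  "M  END"), collapse = "\n")
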