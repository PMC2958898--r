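# Circular arithmetic. All angles are in degrees, 0 = +x axis,
# counter-clockwise, y-up; bearings are normalized to [0, 360).

norm_angle <- function(a) a %% 360

# Signed smallest rotation taking `from` to `to`, in (-180, 180].
angle_diff <- function(from, to) {
  d <- (to - from) %% 360
  ifelse(d > 180, d - 360, d)
}

abs_angle_diff <- function(a, b) abs(angle_diff(a, b))

# Bearing of the vector (dx, dy).
bearing <- function(dx, dy) norm_angle(atan2(dy, dx) * 180 / pi)

deg2rad <- function(a) a * pi / 180

# Collapse angles closer than `tol` to the first-seen representative,
# preserving first-occurrence order.
dedupe_angles <- function(angles, tol = 2) {
  kept <- numeric(0)
  for (a in angles) {
    if (!length(kept) || all(abs_angle_diff(kept, a) > tol)) kept <- c(kept, a)
  }
  kept
}

# Greedy minimum-cost unique assignment of rows (existing angles) to columns
# (template slots): pairs considered in ascending cost order, each row and
# column used at most once. Returns the column index per row, or NULL when
# some row cannot be assigned within `tol`.
greedy_assign <- function(cost, tol = Inf) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0) return(integer(0))
  if (nr > nc) return(NULL)
  ord <- order(cost)
  row_of <- ((ord - 1) %% nr) + 1
  col_of <- ((ord - 1) %/% nr) + 1
  assign <- rep(NA_integer_, nr)
  used_col <- rep(FALSE, nc)
  for (k in seq_along(ord)) {
    if (cost[ord[k]] > tol) break
    r <- row_of[k]; cc <- col_of[k]
    if (is.na(assign[r]) && !used_col[cc]) {
      assign[r] <- cc
      used_col[cc] <- TRUE
    }
  }
  if (anyNA(assign)) NULL else assign
}
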