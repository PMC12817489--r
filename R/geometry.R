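# Small vector-geometry helpers shared by the interaction detectors.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) v / vnorm(v)

# angle at vertex b of the triangle a-b-c, degrees
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# angle between two vectors, degrees
vec_angle_deg <- function(u, v) {
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# acute angle between two directions (lines, not vectors), degrees
line_angle_deg <- function(u, v) {
  a <- vec_angle_deg(u, v)
  min(a, 180 - a)
}

# best-fit plane normal of >= 3 points (rows of m)
plane_normal <- function(m) {
  c0 <- colMeans(m)
  s <- svd(sweep(m, 2, c0))
  s$v[, 3]
}

dist3 <- function(a, b) vnorm(a - b)

# minimum distance between two coordinate matrices (rows = points)
min_cross_dist <- function(a, b) {
  if (is.null(a) || is.null(b) || nrow(a) == 0 || nrow(b) == 0) return(Inf)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}
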