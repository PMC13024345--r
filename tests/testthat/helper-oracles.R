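# Independent oracles used across the suite. These deliberately avoid the
# package's own slicing/execution code paths: brute-force geometry only.

# Closed-form mean radius of points uniformly distributed on one chord of a
# circle of radius R spanned by half-angle phi: with a = R cos(phi),
# b = R sin(phi), mean = (1/2b) [ b sqrt(a^2+b^2) + a^2 ln((b + sqrt(a^2+b^2))/a) ].
chord_mean_radius_oracle <- function(N, D) {
  R <- D / 2
  phi <- pi / N
  a <- R * cos(phi)
  b <- R * sin(phi)
  (b * sqrt(a^2 + b^2) + a^2 * log((b + sqrt(a^2 + b^2)) / a)) / (2 * b)
}

# Radius standard deviation on a chord by dense numeric quadrature
# (trapezoid on 2e5 points; independent of execute_path's sampling).
chord_std_radius_oracle <- function(N, D) {
  R <- D / 2
  phi <- pi / N
  a <- R * cos(phi)
  b <- R * sin(phi)
  t <- seq(-b, b, length.out = 200001)
  r <- sqrt(a^2 + t^2)
  w <- rep(1, length(t)); w[c(1, length(t))] <- 0.5   # trapezoid weights
  m1 <- sum(w * r) / sum(w)
  m2 <- sum(w * r^2) / sum(w)
  sqrt(m2 - m1^2)
}

# Brute-force point-to-triangle distance (projection with edge/vertex
# clamping), minimised over all faces of a mesh.
point_triangle_distance <- function(p, a, b, c) {
  # Ericson-style closest point on triangle
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sqrt(sum((p - (a + ab * v + ac * w))^2))
}

point_to_mesh_distance <- function(pts, mesh) {
  pts <- as.matrix(pts)
  v <- mesh$vertices
  f <- mesh$faces
  apply(pts, 1, function(p) {
    min(vapply(seq_len(nrow(f)), function(i) {
      point_triangle_distance(p, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])
    }, numeric(1)))
  })
}

# Total 3D length of a point sequence given as a tibble with x, y, z.
path_length <- function(df) {
  p <- as.matrix(df[, c("x", "y", "z")])
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# A tiny two-triangle square plate as a raw triangle soup (with duplicated
# corner vertices, as STL stores it).
soup_square <- function(extent = 1, z = 0) {
  list(
    vertices = rbind(
      c(0, 0, z), c(extent, 0, z), c(extent, extent, z),
      c(0, 0, z), c(extent, extent, z), c(0, extent, z)),
    faces = rbind(1:3, 4:6)
  )
}

random_elbow_up_joints <- function(n, seed = 42) {
  set.seed(seed)
  # states with the inter-link bend strictly in the elbow-up half-space:
  # theta3 - theta2 in (-80, 80) degrees keeps gamma in (10, 170) deg
  t2 <- runif(n, -25, 80) * pi / 180
  t3 <- t2 + runif(n, -80, 80) * pi / 180
  t3 <- pmin(pmax(t3, -25 * pi / 180), 105 * pi / 180)
  tibble::tibble(
    theta1 = runif(n, -pi * 8 / 9, pi * 8 / 9),
    theta2 = t2,
    theta3 = t3,
    theta4 = runif(n, -pi, pi)
  )
}
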