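# Fixtures and independent oracles, all built in code.

# Random rotation matrix (uniform via QR of a Gaussian matrix).
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

apply_rigid <- function(P, R, t = c(0, 0, 0)) sweep(P %*% t(R), 2L, t, "+")

# Two aligned/staggered rings of points exactly on a cylinder surface.
exact_cylinder_points <- function(radius = 2, axis = c(0, 0, 1), base = c(0, 0, 0),
                                  heights = c(0, 3), n_per_ring = 4L,
                                  stagger = pi / 4) {
  axis <- axis / sqrt(sum(axis^2))
  a <- if (abs(axis[1]) <= abs(axis[2]) && abs(axis[1]) <= abs(axis[3])) c(1, 0, 0)
       else if (abs(axis[2]) <= abs(axis[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- a - sum(a * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  rows <- list()
  for (h_i in seq_along(heights)) {
    ang <- 2 * pi * (seq_len(n_per_ring) - 1) / n_per_ring + (h_i - 1) * stagger
    rows[[h_i]] <- t(vapply(ang, function(a)
      base + radius * (cos(a) * e1 + sin(a) * e2) + heights[h_i] * axis,
      numeric(3L)))
  }
  do.call(rbind, rows)
}

# Independent plane oracle: centroid + eigenvector of the smallest eigenvalue
# of the scatter matrix.
plane_eigen_oracle <- function(P) {
  ctr <- colMeans(P)
  M <- sweep(P, 2L, ctr)
  ev <- eigen(crossprod(M), symmetric = TRUE)
  n <- ev$vectors[, 3L]
  res <- drop(M %*% n)
  list(normal = n, rms = sqrt(mean(res^2)))
}

cylinder_objective <- function(P, c0, d, r) {
  d <- d / sqrt(sum(d^2))
  Q <- sweep(P, 2L, c0)
  t <- drop(Q %*% d)
  sum((sqrt(rowSums((Q - tcrossprod(t, d))^2)) - r)^2)
}

# Brute-force 5-parameter grid search around the true cylinder parameters
# (pitch 0.01 mm for offsets/radius, 0.5 degrees for direction tilts).
cylinder_grid_min <- function(P, c_true, d_true, r_true,
                              pitch_mm = 0.01, pitch_deg = 0.5, half_width = 2L) {
  d_true <- d_true / sqrt(sum(d_true^2))
  a <- if (abs(d_true[1]) <= abs(d_true[2]) && abs(d_true[1]) <= abs(d_true[3])) c(1, 0, 0)
       else if (abs(d_true[2]) <= abs(d_true[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- a - sum(a * d_true) * d_true; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d_true[2] * e1[3] - d_true[3] * e1[2],
          d_true[3] * e1[1] - d_true[1] * e1[3],
          d_true[1] * e1[2] - d_true[2] * e1[1])
  off <- pitch_mm * (-half_width:half_width)
  tilt <- pitch_deg * pi / 180 * (-half_width:half_width)
  best <- Inf
  for (u in off) for (v in off) for (ta in tilt) for (tb in tilt) for (dr in off) {
    d <- d_true + ta * e1 + tb * e2
    obj <- cylinder_objective(P, c_true + u * e1 + v * e2, d, r_true + dr)
    if (obj < best) best <- obj
  }
  best
}

point_line_distance <- function(p, c0, d) {
  d <- d / sqrt(sum(d^2))
  v <- p - c0
  sqrt(sum((v - sum(v * d) * d)^2))
}

# Small master with untilted axes: pierce points are directly above the bases.
flat_master <- function(positions = matrix(c(0, 0, 12, 0, 24, 0), ncol = 2, byrow = TRUE)) {
  make_master_model(list(positions = positions, tilt_deg = 0))
}

# Build a distance_set directly from given distances over the 4-body pair set.
manual_distance_set <- function(distances_mm, scan_id = "s", scanner_id = "x",
                                n_bodies = 4L) {
  cmb <- utils::combn(n_bodies, 2L)
  a <- cmb[1L, ]; b <- cmb[2L, ]
  ds <- structure(list(scan_id = scan_id, scanner_id = scanner_id,
                       pairs = data.frame(body_a = a, body_b = b,
                                          pair = sprintf("D%d-%d", a, b),
                                          distance_mm = distances_mm,
                                          group = ifelse(b - a == 1L, "short", "long"))),
                  class = "distance_set")
  ds
}

# Long-format accuracy records generator for the statistics tests.
simulate_records <- function(scanner_means, n_per_cell, sd = 1,
                             metric = "trueness", rdist = rnorm) {
  rows <- list()
  for (s in names(scanner_means)) for (g in c("short", "long")) {
    v <- abs(rdist(n_per_cell, scanner_means[[s]], sd))
    rows[[length(rows) + 1L]] <- data.frame(
      scanner_id = s, metric = metric, group = g,
      pair = "D1-2", rep_index = seq_len(n_per_cell),
      signed_error_um = v, abs_error_um = abs(v))
  }
  do.call(rbind, rows)
}
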