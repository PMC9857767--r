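test_that("plane fit recovers exact planes and is rotation-equivariant", {
  set.seed(11)
  pts <- cbind(runif(6, -5, 5), runif(6, -5, 5), 0)
  pf <- fit_plane(pts)
  expect_equal(pf$unit_normal, c(0, 0, 1), tolerance = 1e-12)
  expect_lt(pf$rms_residual, 1e-12)
  expect_lt(abs(pf$point_on_plane[3]), 1e-12)

  # rotated plane: fitted normal = R e3 up to the orientation convention
  R <- rand_rotation()
  pf_r <- fit_plane(apply_rigid(pts, R, c(1, -2, 3)))
  expect_lt(min(sqrt(sum((pf_r$unit_normal - R %*% c(0, 0, 1))^2)),
                sqrt(sum((pf_r$unit_normal + R %*% c(0, 0, 1))^2))), 1e-9)
  expect_lt(pf_r$rms_residual, 1e-9)
})

test_that("plane fit equals the eigen-decomposition oracle on noisy data", {
  set.seed(42)
  for (rep in 1:20) {
    pts <- cbind(runif(6, -5, 5), runif(6, -5, 5), 2)
    pts <- pts + matrix(rnorm(18, 0, 0.01), 6L)
    R <- rand_rotation()
    pts <- apply_rigid(pts, R, rnorm(3))
    pf <- fit_plane(pts)
    orc <- plane_eigen_oracle(pts)
    expect_lt(abs(pf$rms_residual - orc$rms), 1e-12)
    expect_lt(1 - abs(sum(pf$unit_normal * orc$normal)), 1e-12)
  }
})

test_that("plane fit normal orientation follows the +z, +x, +y tie-break", {
  set.seed(3)
  pts <- cbind(runif(8, -5, 5), runif(8, -5, 5), rnorm(8, 0, 0.01))
  expect_gte(fit_plane(pts)$unit_normal[3], 0)
  # vertical plane x = 0: normal has z ~ 0, must point to +x
  pts_v <- cbind(0, runif(8, -5, 5), runif(8, -5, 5))
  expect_gte(fit_plane(pts_v)$unit_normal[1], 0)
})

test_that("plane fit rejects degenerate inputs", {
  expect_error(fit_plane(cbind(1:3, 1, 0)), "at least 4")
  expect_error(fit_plane(cbind(1:6, 2 * (1:6), 3 * (1:6))), "collinear",
               class = "scanmetry_degenerate_geometry_error")
})

test_that("cylinder fit recovers an exact cylinder to machine precision", {
  pts <- exact_cylinder_points(radius = 2, axis = c(0, 0, 1))
  cf <- fit_cylinder(pts)
  expect_equal(cf$radius, 2, tolerance = 1e-9)
  expect_lt(1 - abs(sum(cf$axis_direction * c(0, 0, 1))), 1e-9)
  expect_lt(cf$rms_residual, 1e-9)
  expect_true(cf$converged)
})

test_that("cylinder fit is equivariant under rigid motions", {
  set.seed(7)
  pts <- exact_cylinder_points(radius = 2, axis = c(0, 0, 1)) +
    matrix(rnorm(24, 0, 0.005), 8L)
  cf0 <- fit_cylinder(pts)
  for (rep in 1:5) {
    R <- rand_rotation(); tv <- rnorm(3, 0, 10)
    cf1 <- fit_cylinder(apply_rigid(pts, R, tv))
    expect_equal(cf1$radius, cf0$radius, tolerance = 1e-9)
    expect_equal(cf1$rms_residual, cf0$rms_residual, tolerance = 1e-9)
    expect_lt(1 - abs(sum(cf1$axis_direction * (R %*% cf0$axis_direction))), 1e-9)
    # mapped axis point lies on the fitted axis line
    expect_lt(point_line_distance(drop(R %*% cf0$axis_point + tv),
                                  cf1$axis_point, cf1$axis_direction), 1e-7)
  }
})

test_that("cylinder fit objective beats a brute-force grid around the truth", {
  set.seed(99)
  for (rep in 1:3) {
    pts <- exact_cylinder_points(radius = 2, axis = c(0, 0, 1)) +
      matrix(rnorm(24, 0, 0.005), 8L)
    cf <- fit_cylinder(pts)
    grid_min <- cylinder_grid_min(pts, c(0, 0, 1.5), c(0, 0, 1), 2)
    expect_lte(cf$objective, grid_min + 1e-12)
    # and never exceeds the true cylinder's objective
    expect_lte(cf$objective, cylinder_objective(pts, c(0, 0, 0), c(0, 0, 1), 2))
  }
})

test_that("cylinder fit reports non-convergence instead of failing silently", {
  set.seed(5)
  pts <- exact_cylinder_points() + matrix(rnorm(24, 0, 0.02), 8L)
  cf <- fit_cylinder(pts, init = list(axis_direction = c(0.3, 0.3, 0.9)),
                     max_iter = 1L)
  expect_false(cf$converged)
  expect_true(is.finite(cf$objective))
  expect_error(fit_cylinder(pts[1:5, ]), "at least 6",
               class = "scanmetry_insufficient_points_error")
})

test_that("pierce point intersects axis and plane", {
  cyl_pts <- exact_cylinder_points(radius = 2, axis = c(0, 0, 1))
  cf <- fit_cylinder(cyl_pts)
  pl <- fit_plane(cbind(c(-1, 1, 1, -1, 0, 0.5), c(-1, -1, 1, 1, 0.3, 0), 5))
  ct <- pierce_point(cf, pl, body_id = 1L)
  expect_equal(c(ct$x, ct$y, ct$z), c(0, 0, 5), tolerance = 1e-9)

  # translated axis
  cf2 <- fit_cylinder(exact_cylinder_points(base = c(1, 2, 0)))
  pl3 <- fit_plane(cbind(c(0, 2, 2, 0, 1, 1.5), c(0, 0, 2, 2, 1, 0.5), 3))
  ct2 <- pierce_point(cf2, pl3)
  expect_equal(c(ct2$x, ct2$y, ct2$z), c(1, 2, 3), tolerance = 1e-9)
})

test_that("pierce point satisfies both membership invariants and the closed form", {
  set.seed(21)
  for (rep in 1:10) {
    axis <- unlist(list(rnorm(3))); axis <- axis / sqrt(sum(axis^2))
    base <- rnorm(3, 0, 5)
    cyl <- list(axis_point = base, axis_direction = axis, radius = 2)
    class(cyl) <- "cylinder_fit"
    nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
    if (abs(sum(nrm * axis)) < 1e-3) next
    pl <- list(point_on_plane = rnorm(3, 0, 5), unit_normal = nrm)
    class(pl) <- "plane_fit"
    ct <- pierce_point(cyl, pl)
    p <- c(ct$x, ct$y, ct$z)
    expect_lt(abs(sum((p - pl$point_on_plane) * nrm)), 1e-9)       # on plane
    expect_lt(point_line_distance(p, base, axis), 1e-9)            # on axis
    t_closed <- sum((pl$point_on_plane - base) * nrm) / sum(axis * nrm)
    expect_equal(p, base + t_closed * axis, tolerance = 1e-12)
  }
})

test_that("pierce point rejects an axis parallel to the plane", {
  cyl <- structure(list(axis_point = c(0, 0, 0), axis_direction = c(1, 0, 0),
                        radius = 1), class = "cylinder_fit")
  pl <- structure(list(point_on_plane = c(0, 0, 5), unit_normal = c(0, 0, 1)),
                  class = "plane_fit")
  expect_error(pierce_point(cyl, pl), "parallel",
               class = "scanmetry_no_intersection_error")
})
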