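test_that("extract_centroids recovers noiseless bodies to 1e-9 mm", {
  m <- make_master_model()
  scan <- lapply(m$bodies, sample_touch_points)
  cts <- extract_centroids(scan)
  for (i in seq_along(cts)) {
    truth <- m$centroids[[i]]
    expect_equal(c(cts[[i]]$x, cts[[i]]$y, cts[[i]]$z),
                 c(truth$x, truth$y, truth$z), tolerance = 1e-9)
  }
  d <- attr(cts, "diagnostics")
  expect_true(all(d$converged))
  expect_lt(max(d$cylinder_rms_mm), 1e-9)
})

test_that("missing and duplicated bodies are reported by id", {
  m <- make_master_model()
  scan <- lapply(m$bodies, sample_touch_points)
  expect_error(extract_centroids(scan[c(1, 2, 4)]), "missing body_id\\(s\\): 3",
               class = "scanmetry_missing_body_error")
  expect_error(extract_centroids(scan[c(1, 1, 2)]), "duplicate")
})

test_that("centroid noise matches the closed-form plane-average oracle", {
  # untilted body: the pierce point's z error is the mean of the 6 top-face
  # z noises, so sd_z = sigma/sqrt(6); the 3D RMS is bounded by the single
  # point noise and by the all-points average sigma/sqrt(14)
  m <- make_master_model(list(positions = matrix(c(0, 0), 1), tilt_deg = 0))
  body <- m$bodies[[1]]
  sigma <- 0.01
  set.seed(314)
  nrep <- 400L
  disp <- t(vapply(seq_len(nrep), function(r) {
    cps <- sample_touch_points(body, noise_sd = sigma)
    ct <- extract_centroids(list(cps))[[1]]
    c(ct$x - m$centroids[[1]]$x, ct$y - m$centroids[[1]]$y,
      ct$z - m$centroids[[1]]$z)
  }, numeric(3L)))
  sd_z <- sd(disp[, 3])
  se_sd <- (sigma / sqrt(6)) / sqrt(2 * nrep)
  expect_lt(abs(sd_z - sigma / sqrt(6)), 3 * se_sd)
  rms <- sqrt(mean(rowSums(disp^2)))
  expect_gt(rms, sigma / sqrt(14))
  # upper bound: lateral centroid error is amplified by the lever arm from the
  # wall-ring mid-height (0.55 h) to the top plane (h) over half the ring
  # separation (0.2 h), i.e. a factor (1 - 0.55) / 0.2 = 2.25 per component
  lever <- (1 - 0.55) / 0.2
  expect_lt(rms, (1 + lever) * sigma)
})

test_that("pairwise distances follow the Euclidean formula", {
  mk <- function(id, x, y, z) structure(list(body_id = id, x = x, y = y, z = z),
                                        class = "centroid")
  ds <- pairwise_distances(list(mk(1L, 0, 0, 0), mk(2L, 3, 4, 0)))
  expect_equal(ds$pairs$distance_mm, 5)
  cts4 <- list(mk(1L, 0, 0, 0), mk(2L, 3, 4, 0), mk(3L, 1, 1, 1), mk(4L, -2, 5, 3))
  expect_equal(nrow(pairwise_distances(cts4)$pairs), 6L)
  expect_error(pairwise_distances(list(mk(1L, 0, 0, 0), mk(1L, 1, 1, 1))),
               "duplicate")
  expect_error(pairwise_distances(list(mk(1L, 0, 0, 0))), "at least 2")
})

test_that("distances are invariant under rigid motion and scale exactly", {
  set.seed(8)
  for (rep in 1:20) {
    X <- matrix(rnorm(12, 0, 20), 4L)
    mk <- function(i, p) structure(list(body_id = i, x = p[1], y = p[2], z = p[3]),
                                   class = "centroid")
    cts <- lapply(1:4, function(i) mk(i, X[i, ]))
    d0 <- pairwise_distances(cts)$pairs$distance_mm
    R <- rand_rotation(); tv <- rnorm(3, 0, 50)
    Xr <- apply_rigid(X, R, tv)
    dr <- pairwise_distances(lapply(1:4, function(i) mk(i, Xr[i, ])))$pairs$distance_mm
    expect_lt(max(abs(dr - d0)), 1e-12 * max(1, max(d0)))
    s <- runif(1, 0.5, 2)
    dsc <- pairwise_distances(lapply(1:4, function(i) mk(i, s * X[i, ])))$pairs$distance_mm
    expect_equal(dsc, s * d0, tolerance = 1e-14)
  }
})

test_that("distance sets satisfy symmetry counts and the triangle inequality", {
  set.seed(12)
  X <- matrix(rnorm(15, 0, 10), 5L)
  mk <- function(i) structure(list(body_id = i, x = X[i, 1], y = X[i, 2], z = X[i, 3]),
                              class = "centroid")
  ds <- classify_distances(pairwise_distances(lapply(1:5, mk)))
  p <- ds$pairs
  expect_equal(nrow(p), choose(5, 2))
  expect_equal(sum(p$group == "short") + sum(p$group == "long"), choose(5, 2))
  dist_of <- function(a, b) p$distance_mm[(p$body_a == a & p$body_b == b) |
                                          (p$body_a == b & p$body_b == a)]
  for (i in 1:3) for (j in (i + 1):4) for (k in (j + 1):5)
    expect_lte(dist_of(i, k), dist_of(i, j) + dist_of(j, k) + 1e-12)
})

test_that("classification matches the adjacency rule of the scan progression", {
  mk <- function(i, x) structure(list(body_id = i, x = x, y = 0, z = 0),
                                 class = "centroid")
  ds4 <- pairwise_distances(lapply(1:4, function(i) mk(i, 10 * i)))
  cl <- classify_distances(ds4)
  short <- cl$pairs$pair[cl$pairs$group == "short"]
  long <- cl$pairs$pair[cl$pairs$group == "long"]
  expect_setequal(short, c("D1-2", "D2-3", "D3-4"))
  expect_setequal(long, c("D1-3", "D1-4", "D2-4"))

  # reversing the progression leaves adjacency unchanged
  cl_rev <- classify_distances(ds4, progression_order = 4:1)
  expect_identical(cl$pairs$group, cl_rev$pairs$group)

  ds3 <- pairwise_distances(lapply(1:3, function(i) mk(i, 10 * i)))
  cl3 <- classify_distances(ds3, progression_order = c(1, 2, 3))
  expect_setequal(cl3$pairs$pair[cl3$pairs$group == "short"], c("D1-2", "D2-3"))
  expect_setequal(cl3$pairs$pair[cl3$pairs$group == "long"], "D1-3")

  expect_error(classify_distances(ds4, progression_order = c(1, 2, 3)),
               "permutation")
  expect_error(classify_distances(ds4, progression_order = c(1, 2, 3, 3)),
               "permutation")
})
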