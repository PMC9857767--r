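# Synthetic study generator. The raw scans behind the published study design
# are not publicly deposited, so this module builds a master geometry (a
# mandibular arch with four near-parallel implant scan bodies at the right and
# left canine and molar positions) and simulates scanner output with the error
# structure the analysis assumes: a global scale bias, cumulative stitching
# drift along the scan progression, and per-point isotropic noise.

direction_from_tilt <- function(tilt_deg, azimuth_deg) {
  t <- tilt_deg * pi / 180
  a <- azimuth_deg * pi / 180
  c(sin(t) * cos(a), sin(t) * sin(a), cos(t))
}

#' Construct the synthetic master geometry
#'
#' Deterministically builds the idealized master model: one cylinder-plus-top-
#' disc scan body per implant site. Default layout: four bodies on a
#' mandibular arch curve at the right molar, right canine, left canine and
#' left molar positions (body ids 1-4 along the scan progression), radius 3 mm,
#' top face 10 mm above the base, axes tilted 1 degree at staggered azimuths
#' (all mutual axis angles <= 2 degrees). The default inter-centroid distances
#' are approximately \{20, 16, 20\} mm for the short (adjacent) pairs and
#' \{32.3, 32.3, 40\} mm for the long (cross-arch) pairs. Ground-truth pierce
#' points and the classified true distances are computed analytically.
#'
#' @param config named list overriding any of: `positions` (k x 2 or k x 3
#'   matrix of base positions, mm), `body_id`, `radius` (mm), `top_offset`
#'   (mm), `tilt_deg`, `tilt_azimuth_deg` (per body, recycled),
#'   `progression_order`.
#' @return Object of class `master_geometry`: per-body geometry (`bodies`),
#'   the analytic `centroids`, and `truth`, a classified `distance_set` of the
#'   true inter-centroid distances (scanner id `"truth"`).
#' @export
make_master_model <- function(config = list()) {
  defaults <- list(
    positions = matrix(c(20, 0,  8, 16,  -8, 16,  -20, 0), ncol = 2L, byrow = TRUE),
    body_id = NULL,
    radius = 3,
    top_offset = 10,
    tilt_deg = 1,
    tilt_azimuth_deg = c(0, 90, 180, 270),
    progression_order = NULL)
  cfg <- utils::modifyList(defaults, config)
  pos <- as.matrix(cfg$positions)
  k <- nrow(pos)
  if (ncol(pos) == 2L) pos <- cbind(pos, 0)
  ids <- if (is.null(cfg$body_id)) seq_len(k) else as.integer(cfg$body_id)
  if (anyDuplicated(ids) || length(ids) != k)
    scanmetry_error("body ids must be unique, one per position",
                    "scanmetry_validation_error")
  tilt <- rep_len(cfg$tilt_deg, k)
  azim <- rep_len(cfg$tilt_azimuth_deg, k)

  bodies <- lapply(seq_len(k), function(i) {
    list(body_id = ids[i],
         base = as.numeric(pos[i, ]),
         axis = direction_from_tilt(tilt[i], azim[i]),
         radius = cfg$radius,
         top_offset = cfg$top_offset)
  })
  # overlapping bodies are a construction error
  if (k >= 2L) {
    base_d <- as.matrix(stats::dist(pos))
    if (min(base_d[upper.tri(base_d)]) <= 2 * cfg$radius)
      scanmetry_error("overlapping bodies: base spacing must exceed twice the radius",
                      "scanmetry_validation_error")
  }
  centroids <- lapply(bodies, function(b) {
    p <- b$base + b$top_offset * b$axis
    structure(list(body_id = b$body_id, x = p[1L], y = p[2L], z = p[3L]),
              class = "centroid")
  })
  truth <- if (k >= 2L) classify_distances(
    pairwise_distances(centroids, scan_id = "master", scanner_id = "truth"),
    progression_order = cfg$progression_order) else NULL
  structure(list(bodies = bodies, centroids = centroids, truth = truth,
                 progression_order = if (is.null(cfg$progression_order)) sort(ids)
                                     else cfg$progression_order,
                 config = cfg),
            class = "master_geometry")
}

#' @export
print.master_geometry <- function(x, ...) {
  cat(sprintf("<master_geometry> %d scan bodies, radius %g mm, top offset %g mm\n",
              length(x$bodies), x$bodies[[1L]]$radius, x$bodies[[1L]]$top_offset))
  if (!is.null(x$truth))
    print(x$truth$pairs[c("pair", "group", "distance_mm")], row.names = FALSE)
  invisible(x)
}

#' Define a scanner error model
#'
#' Three error mechanisms, chosen to reproduce the qualitative behavior of
#' optical scanners on long spans: a global `scale_bias` (distances inflated
#' by a factor 1 + s), `stitching_drift_sd` (a cumulative Gaussian random-walk
#' displacement per progression step, the mechanism that makes cross-arch
#' distances worse than adjacent ones), and isotropic `point_noise_sd` on
#' every contact point.
#'
#' @param scanner_id identifier.
#' @param scale_bias unitless (e.g. 5e-4).
#' @param stitching_drift_sd micrometres per progression step (per axis).
#' @param point_noise_sd micrometres per contact point (per axis).
#' @return Object of class `scanner_model`.
#' @export
scanner_model <- function(scanner_id, scale_bias = 0, stitching_drift_sd = 0,
                          point_noise_sd = 0) {
  if (stitching_drift_sd < 0 || point_noise_sd < 0)
    scanmetry_error("noise SDs must be non-negative", "scanmetry_validation_error")
  structure(list(scanner_id = as.character(scanner_id),
                 scale_bias = scale_bias,
                 stitching_drift_sd = stitching_drift_sd,
                 point_noise_sd = point_noise_sd),
            class = "scanner_model")
}

#' Default suite of nine synthetic scanners
#'
#' Two laboratory-scanner-like models (small bias and drift) and seven
#' intraoral-scanner-like models spanning the error magnitudes typical of the
#' device class (trueness from tens to hundreds of micrometres, degrading with
#' inter-implant span). Parameters are fixed package defaults, documented in
#' the methods vignette.
#'
#' @return Named list of 9 [scanner_model()] objects.
#' @export
default_scanner_models <- function() {
  specs <- list(
    c(1e-04,  5,  5), c(1.5e-04,  8,  6),               # lab scanners
    c(3e-04, 12, 10), c(5e-04, 15, 12), c(6e-04, 18, 12),
    c(7e-04, 20, 15), c(8e-04, 25, 18), c(5e-03, 30, 20),
    c(3e-03, 60, 30))
  ids <- c("LabScan-A", "LabScan-B", paste0("IOS-", LETTERS[1:7]))
  out <- Map(function(id, s) scanner_model(id, s[1L], s[2L], s[3L]), ids, specs)
  stats::setNames(out, ids)
}

#' Sample touch points on a scan body
#'
#' Emulates the tactile probing protocol: `n_cyl` points in two staggered
#' rings on the cylindrical wall and `n_plane` points with even angular
#' coverage on the top disc, plus isotropic Gaussian noise. Defaults are 8
#' wall + 6 top points per body.
#'
#' @param body one element of a `master_geometry`'s `bodies` list (fields
#'   `body_id`, `base`, `axis`, `radius`, `top_offset`).
#' @param n_cyl number of wall points (>= 6).
#' @param n_plane number of top-face points (>= 4).
#' @param noise_sd isotropic per-coordinate noise SD in mm. Uses the R random
#'   number stream; seed with [set.seed()] for reproducibility.
#' @return A [contact_point_set()].
#' @export
sample_touch_points <- function(body, n_cyl = 8L, n_plane = 6L, noise_sd = 0) {
  if (n_cyl < 6L || n_plane < 4L)
    scanmetry_error("need n_cyl >= 6 and n_plane >= 4", "scanmetry_validation_error")
  fr <- orthonormal_frame(body$axis)
  circle <- function(ang, radius, height) {
    t(vapply(ang, function(a)
      body$base + radius * cos(a) * fr$e1 + radius * sin(a) * fr$e2 + height * body$axis,
      numeric(3L)))
  }
  n1 <- ceiling(n_cyl / 2); n2 <- n_cyl - n1
  cyl <- rbind(circle(2 * pi * (seq_len(n1) - 1) / n1, body$radius, 0.35 * body$top_offset),
               circle(2 * pi * (seq_len(n2) - 1) / n2 + pi / n2, body$radius, 0.75 * body$top_offset))
  pln <- circle(2 * pi * (seq_len(n_plane) - 1) / n_plane + pi / n_plane,
                0.7 * body$radius, body$top_offset)
  if (noise_sd > 0) {
    cyl <- cyl + matrix(stats::rnorm(length(cyl), 0, noise_sd), nrow(cyl))
    pln <- pln + matrix(stats::rnorm(length(pln), 0, noise_sd), nrow(pln))
  }
  contact_point_set(body$body_id, cyl, pln)
}

#' Simulate one scan of the master model
#'
#' Applies the scanner error model to the master geometry and samples labeled
#' contact points: (i) global scaling by 1 + scale_bias about the centroid of
#' the true pierce points, (ii) cumulative stitching drift - the body at
#' progression step k is rigidly displaced by the sum of k i.i.d. Gaussian
#' steps, and (iii) per-point isotropic noise.
#'
#' @param master a `master_geometry`.
#' @param scanner a `scanner_model`.
#' @param scan_id identifier stamped on the result.
#' @param progression_order body ids in scan order (default: the master's).
#' @param n_cyl,n_plane touch points per body.
#' @param seed optional integer seed (calls [set.seed()]).
#' @return List of [contact_point_set()] objects with attributes `scan_id`,
#'   `scanner_id` and `bodies` (the transformed per-body geometry, used for
#'   STL export).
#' @export
simulate_scan <- function(master, scanner, scan_id = "scan1",
                          progression_order = NULL, n_cyl = 8L, n_plane = 6L,
                          seed = NULL) {
  stopifnot(inherits(master, "master_geometry"), inherits(scanner, "scanner_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(progression_order)) progression_order <- master$progression_order
  ids <- vapply(master$bodies, function(b) b$body_id, integer(1L))
  k <- length(ids)
  arch_ctr <- colMeans(centroid_coords(master$centroids))
  s <- scanner$scale_bias
  drift_mm <- scanner$stitching_drift_sd / 1000
  noise_mm <- scanner$point_noise_sd / 1000

  steps <- matrix(if (drift_mm > 0) stats::rnorm(3L * k, 0, drift_mm) else 0, k, 3L)
  disp <- apply(steps, 2L, cumsum)
  if (k == 1L) disp <- matrix(disp, 1L)

  scan <- vector("list", k)
  bodies_out <- vector("list", k)
  for (i in seq_len(k)) {
    b <- master$bodies[[i]]
    step_k <- match(b$body_id, progression_order)
    tb <- b
    tb$base <- arch_ctr + (1 + s) * (b$base - arch_ctr) + disp[step_k, ]
    tb$radius <- (1 + s) * b$radius
    tb$top_offset <- (1 + s) * b$top_offset
    bodies_out[[i]] <- tb
    scan[[i]] <- sample_touch_points(tb, n_cyl = n_cyl, n_plane = n_plane,
                                     noise_sd = noise_mm)
  }
  attr(scan, "scan_id") <- scan_id
  attr(scan, "scanner_id") <- scanner$scanner_id
  attr(scan, "bodies") <- bodies_out
  scan
}

#' Simulate a full accuracy study
#'
#' Generates the complete study bundle: `n_scans` repeated scans per scanner,
#' plus a CMM-style reference measurement of the master (replicated noisy
#' distance measurements with SD = MPE/3 at each distance's length, averaged),
#' all deterministically derived from one master seed (each scan gets its own
#' substream so it is independently reproducible).
#'
#' @param master a `master_geometry`.
#' @param scanners list of `scanner_model`s (default: the nine-package suite).
#' @param n_scans repeated scans per scanner (default 10).
#' @param seed master integer seed.
#' @param reference `"cmm"` (replicate-averaged noisy reference, the default)
#'   or `"truth"` (exact analytic distances).
#' @param cmm_replicates number of reference replicates (default 10).
#' @param out_dir optional directory: writes contact-point CSVs, reference
#'   CSVs and a JSON manifest via [write_study()].
#' @param stl also write one binary STL mesh per scan (requires `out_dir`).
#' @return Object of class `scan_study`: `master`, `scanners`, nested `scans`
#'   (scanner -> scan -> contact point sets), `reference` (a classified
#'   `distance_set`), `cmm_replicates` (long data.frame of the raw reference
#'   replicates with their MPE bound), `seed`, `reference_mode`, `out_dir`.
#' @export
simulate_study <- function(master = make_master_model(),
                           scanners = default_scanner_models(),
                           n_scans = 10L, seed = 1L,
                           reference = c("cmm", "truth"),
                           cmm_replicates = 10L,
                           out_dir = NULL, stl = FALSE) {
  reference <- match.arg(reference)
  seed <- as.integer(seed)
  truth <- master$truth

  set.seed(seed %% 2147480000L)
  reps <- do.call(rbind, lapply(seq_len(cmm_replicates), function(r) {
    d <- truth$pairs$distance_mm
    mpe <- cmm_mpe(d)
    data.frame(replicate = r, pair = truth$pairs$pair, group = truth$pairs$group,
               distance_mm = d + stats::rnorm(length(d), 0, (mpe / 3) / 1000),
               mpe_um = mpe)
  }))
  ref <- truth
  ref$scanner_id <- "CMM"
  ref$scan_id <- "reference"
  if (reference == "cmm") {
    agg <- tapply(reps$distance_mm, reps$pair, mean)
    ref$pairs$distance_mm <- as.numeric(agg[ref$pairs$pair])
  }
  ref$pairs$mpe_um <- cmm_mpe(ref$pairs$distance_mm)

  scans <- lapply(seq_along(scanners), function(si) {
    lapply(seq_len(n_scans), function(j) {
      sub_seed <- (seed + 7919L * si + 131L * j) %% 2147480000L
      simulate_scan(master, scanners[[si]], scan_id = sprintf("scan%02d", j),
                    seed = sub_seed)
    })
  })
  names(scans) <- vapply(scanners, function(sc) sc$scanner_id, character(1L))

  bundle <- structure(list(master = master, scanners = scanners,
                           n_scans = as.integer(n_scans),
                           scans = scans, reference = ref,
                           cmm_replicates = reps, seed = seed,
                           reference_mode = reference,
                           out_dir = out_dir),
                      class = "scan_study")
  if (!is.null(out_dir)) write_study(bundle, out_dir, stl = stl)
  bundle
}

#' @export
print.scan_study <- function(x, ...) {
  cat(sprintf("<scan_study> %d scanners x %d scans, %d bodies, reference: %s, seed %d\n",
              length(x$scanners), x$n_scans, length(x$master$bodies),
              x$reference_mode, x$seed))
  invisible(x)
}
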