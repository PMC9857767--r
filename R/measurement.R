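# Measurement layer: one scan (a set of labeled contact-point sets) is turned
# into pierce-point centroids and the classified inter-implant distances.

#' Extract pierce-point centroids from one scan
#'
#' Runs the feature-fitting chain for every scan body in a scan: total
#' least-squares plane fit on the top-face points, Gauss-Newton cylinder fit on
#' the wall points (initialized with the plane normal, since the top face is
#' orthogonal to the axis by construction), then the axis/plane intersection.
#'
#' @param scan list of [contact_point_set()] objects, one per body, unique
#'   body ids.
#' @param expected_bodies integer vector of body ids that must be present.
#'   Defaults to `1:max(body ids)` so a gap in the numbering is reported as a
#'   missing body.
#' @return List of `centroid` objects (ordered by body id) with a
#'   `diagnostics` attribute: a data.frame of per-body fit residuals,
#'   convergence flags and iteration counts.
#' @export
extract_centroids <- function(scan, expected_bodies = NULL) {
  if (!length(scan) || !all(vapply(scan, inherits, logical(1L), "contact_point_set")))
    scanmetry_error("scan must be a non-empty list of contact_point_set objects",
                    "scanmetry_validation_error")
  ids <- vapply(scan, function(b) b$body_id, integer(1L))
  if (anyDuplicated(ids))
    scanmetry_error(sprintf("duplicate body_id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                    "scanmetry_validation_error")
  if (is.null(expected_bodies) && all(ids >= 1L)) expected_bodies <- seq_len(max(ids))
  missing <- setdiff(expected_bodies, ids)
  if (length(missing))
    scanmetry_error(sprintf("missing body_id(s): %s", paste(missing, collapse = ", ")),
                    "scanmetry_missing_body_error")

  ord <- order(ids)
  scan <- scan[ord]
  out <- vector("list", length(scan))
  diag_rows <- vector("list", length(scan))
  for (i in seq_along(scan)) {
    b <- scan[[i]]
    res <- tryCatch({
      pf <- fit_plane(b$plane_points)
      cf <- fit_cylinder(b$cylinder_points, init = list(axis_direction = pf$unit_normal))
      list(pf = pf, cf = cf, ct = pierce_point(cf, pf, body_id = b$body_id))
    }, scanmetry_error = function(e) {
      scanmetry_error(sprintf("body %d: %s", b$body_id, conditionMessage(e)),
                      class(e)[1L])
    })
    out[[i]] <- res$ct
    diag_rows[[i]] <- data.frame(body_id = b$body_id,
                                 plane_rms_mm = res$pf$rms_residual,
                                 cylinder_rms_mm = res$cf$rms_residual,
                                 cylinder_radius_mm = res$cf$radius,
                                 converged = res$cf$converged,
                                 iterations = res$cf$iterations)
  }
  attr(out, "diagnostics") <- do.call(rbind, diag_rows)
  out
}

pair_label <- function(a, b) sprintf("D%s-%s", a, b)

#' All pairwise inter-centroid distances of one scan
#'
#' Euclidean distances
#' d = sqrt((x1-x2)^2 + (y1-y2)^2 + (z1-z2)^2)
#' between every unordered pair of scan-body centroids. For k bodies this
#' yields choose(k, 2) distances (6 for the standard 4-implant arch).
#'
#' @param centroids list of `centroid` objects with distinct body ids (at
#'   least 2).
#' @param scan_id,scanner_id identifiers stamped on the result.
#' @return An object of class `distance_set`: identifiers plus a `pairs`
#'   data.frame with columns `body_a`, `body_b`, `pair` (e.g. `"D1-2"`),
#'   `distance_mm` and `group` (`NA` until [classify_distances()] is applied).
#' @export
pairwise_distances <- function(centroids, scan_id = "scan", scanner_id = "scanner") {
  if (length(centroids) < 2L)
    scanmetry_error("need at least 2 centroids", "scanmetry_validation_error")
  ids <- vapply(centroids, function(ct) ct$body_id, integer(1L))
  if (anyDuplicated(ids))
    scanmetry_error("duplicate body_ids among centroids", "scanmetry_validation_error")
  ord <- order(ids)
  ids <- ids[ord]
  xyz <- centroid_coords(centroids[ord])
  cmb <- utils::combn(length(ids), 2L)
  a <- ids[cmb[1L, ]]
  b <- ids[cmb[2L, ]]
  d <- sqrt(rowSums((xyz[cmb[1L, ], , drop = FALSE] - xyz[cmb[2L, ], , drop = FALSE])^2))
  structure(list(scan_id = scan_id,
                 scanner_id = scanner_id,
                 pairs = data.frame(body_a = a, body_b = b,
                                    pair = pair_label(a, b),
                                    distance_mm = d,
                                    group = NA_character_)),
            class = "distance_set")
}

#' Classify distances into short and long groups
#'
#' Pairs of bodies adjacent in the scan progression order form the short
#' group; all other (cross-arch) pairs form the long group. For the canonical
#' order 1-2-3-4 this gives short = \{D1-2, D2-3, D3-4\} and
#' long = \{D1-3, D1-4, D2-4\}. Adjacency is invariant to reversing the
#' progression.
#'
#' @param ds a `distance_set`.
#' @param progression_order permutation of the body ids in scan order;
#'   defaults to ascending body id.
#' @return The `distance_set` with the `group` column filled in and a
#'   `step_sep` column (number of progression steps between the two bodies).
#' @export
classify_distances <- function(ds, progression_order = NULL) {
  stopifnot(inherits(ds, "distance_set"))
  ids <- sort(unique(c(ds$pairs$body_a, ds$pairs$body_b)))
  if (is.null(progression_order)) progression_order <- ids
  if (length(progression_order) != length(ids) ||
      !setequal(progression_order, ids) || anyDuplicated(progression_order))
    scanmetry_error("progression_order must be a permutation of the body ids",
                    "scanmetry_validation_error")
  pos <- match(ds$pairs$body_a, progression_order) -
         match(ds$pairs$body_b, progression_order)
  ds$pairs$step_sep <- abs(pos)
  ds$pairs$group <- ifelse(abs(pos) == 1L, "short", "long")
  ds
}

#' @export
print.distance_set <- function(x, ...) {
  cat(sprintf("<distance_set> scanner %s, scan %s\n", x$scanner_id, x$scan_id))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.distance_set <- function(x, ...) {
  cbind(data.frame(scan_id = x$scan_id, scanner_id = x$scanner_id),
        x$pairs)
}
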