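# File formats, study serialization and the end-to-end pipeline.
# Coordinates are right-handed model-frame mm throughout; CSVs carry full
# double precision (15 significant digits); report-layer CSVs round errors to
# 0.1 um, and nothing earlier is ever rounded.

#' Write labeled contact points to CSV
#'
#' Schema: `body_id`, `surface` (`cylinder`/`plane`), `x_mm`, `y_mm`, `z_mm`;
#' header mandatory, decimal point, UTF-8.
#'
#' @param scan list of [contact_point_set()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contact_points <- function(scan, path) {
  rows <- lapply(scan, function(b) {
    rbind(data.frame(body_id = b$body_id, surface = "cylinder",
                     x_mm = b$cylinder_points[, 1L], y_mm = b$cylinder_points[, 2L],
                     z_mm = b$cylinder_points[, 3L]),
          data.frame(body_id = b$body_id, surface = "plane",
                     x_mm = b$plane_points[, 1L], y_mm = b$plane_points[, 2L],
                     z_mm = b$plane_points[, 3L]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read labeled contact points from CSV
#'
#' @param path CSV with columns `body_id`, `surface`, `x_mm`, `y_mm`, `z_mm`.
#' @return List of [contact_point_set()] objects ordered by body id.
#' @export
read_contact_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("body_id", "surface", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    scanmetry_error(sprintf("contact-point CSV must have columns: %s",
                            paste(need, collapse = ", ")),
                    "scanmetry_validation_error")
  if (!all(df$surface %in% c("cylinder", "plane")))
    scanmetry_error("surface must be 'cylinder' or 'plane'",
                    "scanmetry_validation_error")
  lapply(sort(unique(df$body_id)), function(id) {
    sub <- df[df$body_id == id, ]
    contact_point_set(id,
                      as.matrix(sub[sub$surface == "cylinder", c("x_mm", "y_mm", "z_mm")]),
                      as.matrix(sub[sub$surface == "plane", c("x_mm", "y_mm", "z_mm")]))
  })
}

#' Write a simulated study to disk
#'
#' Lays out one contact-point CSV per scan (`scans/<scanner>/<scan>.csv`),
#' the reference distances (`reference.csv`), the raw CMM-style replicates
#' (`cmm_replicates.csv`), optional binary STL meshes (`stl/`), and a JSON
#' manifest tying them together.
#'
#' @param study a `scan_study`.
#' @param dir output directory (created).
#' @param stl also write one binary STL per scan.
#' @return Manifest path, invisibly.
#' @export
write_study <- function(study, dir, stl = FALSE) {
  stopifnot(inherits(study, "scan_study"))
  dir.create(file.path(dir, "scans"), recursive = TRUE, showWarnings = FALSE)
  if (stl) dir.create(file.path(dir, "stl"), showWarnings = FALSE)
  files <- list()
  for (sc in names(study$scans)) {
    dir.create(file.path(dir, "scans", sc), showWarnings = FALSE)
    for (j in seq_along(study$scans[[sc]])) {
      scan <- study$scans[[sc]][[j]]
      rel <- file.path("scans", sc, paste0(attr(scan, "scan_id"), ".csv"))
      write_contact_points(scan, file.path(dir, rel))
      files[[length(files) + 1L]] <- list(scanner_id = sc,
                                          scan_id = attr(scan, "scan_id"),
                                          path = rel)
      if (stl) {
        stl_rel <- file.path("stl", sprintf("%s_%s.stl", sc, attr(scan, "scan_id")))
        write_stl(scan_mesh(attr(scan, "bodies")), file.path(dir, stl_rel))
        files[[length(files)]]$stl <- stl_rel
      }
    }
  }
  ref_df <- as.data.frame(study$reference)
  utils::write.csv(ref_df, file.path(dir, "reference.csv"), row.names = FALSE)
  utils::write.csv(study$cmm_replicates, file.path(dir, "cmm_replicates.csv"),
                   row.names = FALSE)
  manifest <- list(design = list(scanners = names(study$scans),
                                 n_scans = study$n_scans,
                                 bodies = vapply(study$master$bodies,
                                                 function(b) b$body_id, integer(1L)),
                                 progression_order = study$master$progression_order),
                   files = files,
                   reference_file = "reference.csv",
                   cmm_replicates_file = "cmm_replicates.csv",
                   seed = study$seed,
                   reference_mode = study$reference_mode,
                   units = "mm",
                   version = as.character(utils::packageVersion("scanmetry")))
  write_manifest(manifest, file.path(dir, "manifest.json"))
  invisible(file.path(dir, "manifest.json"))
}

#' Write a study manifest as JSON
#' @param manifest manifest list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a study manifest
#'
#' Every file the manifest references must exist relative to the manifest's
#' directory.
#'
#' @param path manifest JSON path.
#' @return Manifest list with attribute `dir`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!length(m) || is.null(m$design) || !length(m$files))
    scanmetry_error("empty or incomplete manifest", "scanmetry_validation_error")
  base <- dirname(path)
  refd <- c(vapply(m$files, function(f) f$path, character(1L)),
            m$reference_file, m$cmm_replicates_file)
  missing <- refd[!file.exists(file.path(base, refd))]
  if (length(missing))
    scanmetry_error(sprintf("manifest references missing file(s): %s",
                            paste(utils::head(missing, 3L), collapse = ", ")),
                    "scanmetry_validation_error")
  attr(m, "dir") <- base
  m
}

#' Load a written study from its manifest
#'
#' @param path manifest JSON path (or the study directory containing
#'   `manifest.json`).
#' @return List with `scans` (scanner -> scan -> contact point sets),
#'   `reference` (classified `distance_set`), `manifest`.
#' @export
read_study <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  m <- read_manifest(path)
  base <- attr(m, "dir")
  scans <- stats::setNames(vector("list", length(m$design$scanners)),
                           m$design$scanners)
  for (f in m$files) {
    scan <- read_contact_points(file.path(base, f$path))
    attr(scan, "scan_id") <- f$scan_id
    attr(scan, "scanner_id") <- f$scanner_id
    scans[[f$scanner_id]] <- c(scans[[f$scanner_id]], list(scan))
  }
  ref_df <- utils::read.csv(file.path(base, m$reference_file),
                            stringsAsFactors = FALSE)
  ref <- structure(list(scan_id = "reference", scanner_id = "CMM",
                        pairs = ref_df[setdiff(names(ref_df),
                                               c("scan_id", "scanner_id"))]),
                   class = "distance_set")
  list(scans = scans, reference = ref, manifest = m)
}

#' Run the full accuracy pipeline
#'
#' simulate/load -> measure -> analyze -> report, end to end: extracts
#' pierce-point centroids for every scan, computes and classifies the
#' inter-implant distances, builds trueness and precision records against the
#' reference, summarizes them, fits the Box-Cox two-factor model per metric
#' and attaches Tukey letters to the descriptive tables. Deterministic given
#' its inputs, so a rerun writes byte-identical CSVs.
#'
#' @param study a `scan_study` (from [simulate_study()]), or a path to a
#'   written study directory / manifest.
#' @param out_dir optional output directory for the result CSVs
#'   (`distances.csv`, `accuracy_records.csv`, `summary_<metric>.csv`,
#'   `anova_<metric>.csv`, `posthoc_<metric>.csv`).
#' @param alpha significance level for the post hoc letters.
#' @param boxcox_offset offset (um) added to absolute errors before the
#'   Box-Cox transform.
#' @param reference `"cmm"` uses the study's replicate-averaged reference;
#'   `"truth"` uses the exact analytic distances (in-memory studies only).
#' @param progression_order body ids in scan order (default: the study's).
#' @param lambda optional fixed Box-Cox lambda (length 1, or named vector with
#'   entries `trueness` and `precision`); default estimates per metric.
#' @param plots also write mean-error plots (PDF) to `out_dir`.
#' @return List with `distances` (data.frame), `records`, `summaries` (with
#'   Tukey letters and a >150 um annotation flag), `fits` (per metric
#'   `accuracy_lm`), `posthoc` (per metric `tukey_posthoc`), `reference`.
#' @export
run_pipeline <- function(study, out_dir = NULL, alpha = 0.05,
                         boxcox_offset = 0.5,
                         reference = c("cmm", "truth"),
                         progression_order = NULL, lambda = NULL,
                         plots = FALSE) {
  reference <- match.arg(reference)
  if (is.character(study)) study <- read_study(study)
  scans <- study$scans
  if (is.null(scans) || !length(scans))
    scanmetry_error("study contains no scans", "scanmetry_validation_error")
  if (is.null(progression_order)) {
    progression_order <- if (!is.null(study$master)) study$master$progression_order
                         else study$manifest$design$progression_order
  }
  ref_ds <- if (reference == "truth") {
    if (is.null(study$master))
      scanmetry_error("truth reference requires an in-memory scan_study",
                      "scanmetry_validation_error")
    study$master$truth
  } else study$reference

  bodies <- sort(unique(c(ref_ds$pairs$body_a, ref_ds$pairs$body_b)))
  measured <- lapply(names(scans), function(sc) {
    lapply(scans[[sc]], function(scan) {
      cts <- extract_centroids(scan, expected_bodies = bodies)
      classify_distances(
        pairwise_distances(cts, scan_id = attr(scan, "scan_id"),
                           scanner_id = sc),
        progression_order = progression_order)
    })
  })
  names(measured) <- names(scans)

  distances <- do.call(rbind, lapply(measured, function(l)
    do.call(rbind, lapply(l, as.data.frame))))
  rownames(distances) <- NULL

  records <- do.call(rbind, lapply(measured, function(l)
    rbind(trueness_errors(l, ref_ds), precision_errors(l))))
  rownames(records) <- NULL

  lam <- function(metric) {
    if (is.null(lambda)) NULL
    else if (length(lambda) == 1L && is.null(names(lambda))) unname(lambda)
    else unname(lambda[[metric]])
  }
  fits <- list(trueness = fit_accuracy_lm(records, "trueness",
                                          lambda = lam("trueness"),
                                          offset = boxcox_offset),
               precision = fit_accuracy_lm(records, "precision",
                                           lambda = lam("precision"),
                                           offset = boxcox_offset))
  posthoc <- lapply(fits, tukey_posthoc, alpha = alpha)

  summaries <- lapply(names(fits), function(metric) {
    s <- descriptive_stats(records[records$metric == metric, ])
    lt <- posthoc[[metric]]$letters
    s$letters <- lt$letters[match(paste(s$scanner_id, s$group),
                                  paste(lt$scanner, lt$group))]
    s$flag_over_150um <- s$mean_um > 150
    s
  })
  names(summaries) <- names(fits)

  result <- list(distances = distances, records = records,
                 summaries = summaries, fits = fits, posthoc = posthoc,
                 reference = ref_ds, alpha = alpha)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, nm) utils::write.csv(df, file.path(out_dir, nm),
                                              row.names = FALSE)
    wcsv(distances, "distances.csv")
    wcsv(records, "accuracy_records.csv")
    for (metric in names(summaries)) {
      s <- summaries[[metric]]
      # report layer: errors rounded to 0.1 um, as in the field's tables
      for (col in c("median_um", "iqr_um", "mean_um", "sd_um"))
        s[[col]] <- round(s[[col]], 1L)
      wcsv(s, sprintf("summary_%s.csv", metric))
      wcsv(fits[[metric]]$anova, sprintf("anova_%s.csv", metric))
      wcsv(posthoc[[metric]]$contrasts, sprintf("posthoc_%s.csv", metric))
    }
    if (plots) {
      for (metric in names(summaries))
        plot_mean_errors(summaries[[metric]], metric,
                         file = file.path(out_dir,
                                          sprintf("mean_errors_%s.pdf", metric)))
    }
  }
  result
}

#' Mean absolute error bar plot
#'
#' Mean absolute error per scanner and distance group with +/- 1 SD error
#' bars; a visual companion to the descriptive tables.
#'
#' @param summary a descriptive-summary data.frame (one metric).
#' @param metric label for the y axis/title.
#' @param file optional PDF path; plots to the active device when `NULL`.
#' @return `invisible(NULL)`.
#' @export
plot_mean_errors <- function(summary, metric = "trueness", file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 8, height = 5)
    on.exit(grDevices::dev.off())
  }
  groups <- c("short", "long")
  scanners <- sort(unique(summary$scanner_id))
  mt <- sapply(groups, function(g)
    summary$mean_um[match(paste(scanners, g),
                          paste(summary$scanner_id, summary$group))])
  st <- sapply(groups, function(g)
    summary$sd_um[match(paste(scanners, g),
                        paste(summary$scanner_id, summary$group))])
  bp <- graphics::barplot(t(mt), beside = TRUE, names.arg = scanners,
                          las = 2, col = c("grey80", "grey40"),
                          ylim = c(0, max(mt + st, na.rm = TRUE) * 1.15),
                          ylab = sprintf("mean absolute %s error (um)", metric))
  graphics::arrows(bp, t(mt) - t(st), bp, t(mt) + t(st),
                   angle = 90, code = 3, length = 0.03)
  graphics::legend("topleft", legend = groups, fill = c("grey80", "grey40"),
                   bty = "n")
  invisible(NULL)
}
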