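# Trueness and precision error construction. All geometry is computed in mm;
# errors are converted to micrometres (the field's reporting unit) here, at
# the record level, and nowhere earlier.

check_pair_match <- function(pairs_a, pairs_b, what) {
  if (!setequal(pairs_a, pairs_b) || length(pairs_a) != length(pairs_b))
    scanmetry_error(sprintf("pair-set mismatch between %s", what),
                    "scanmetry_validation_error")
}

#' Trueness errors of repeated scans against a reference
#'
#' Trueness is closeness to the accepted reference value: for every scan and
#' every inter-implant distance, the signed error is (scan distance minus
#' reference distance), converted to micrometres; statistics downstream use the
#' absolute value, but the signed error is retained because signed and
#' absolute summaries answer different questions (signed errors of opposite
#' sign would otherwise cancel).
#'
#' @param scans list of `distance_set` objects for one scanner (classified).
#' @param reference a `distance_set` holding the reference (e.g. CMM-measured)
#'   distances over the same pairs.
#' @return A long-format data.frame of accuracy records with columns
#'   `scanner_id`, `metric` (`"trueness"`), `group`, `pair`, `rep_index`,
#'   `signed_error_um`, `abs_error_um`; one row per scan x pair.
#' @export
trueness_errors <- function(scans, reference) {
  stopifnot(length(scans) >= 1L, inherits(reference, "distance_set"))
  ref <- reference$pairs
  records <- lapply(seq_along(scans), function(i) {
    ds <- scans[[i]]
    stopifnot(inherits(ds, "distance_set"))
    check_pair_match(ds$pairs$pair, ref$pair, "scan and reference")
    m <- match(ds$pairs$pair, ref$pair)
    signed <- (ds$pairs$distance_mm - ref$distance_mm[m]) * 1000
    grp <- ds$pairs$group
    if (all(is.na(grp))) grp <- ref$group[m]
    data.frame(scanner_id = ds$scanner_id,
               metric = "trueness",
               group = grp,
               pair = ds$pairs$pair,
               rep_index = as.character(ds$scan_id),
               signed_error_um = signed,
               abs_error_um = abs(signed))
  })
  do.call(rbind, records)
}

#' Precision errors from repeated scans
#'
#' Precision is closeness of repeated measurements to each other; no reference
#' is needed. For each inter-implant distance, all choose(m, 2) absolute
#' pairwise differences |d_i - d_j| between the m repeated scans are recorded
#' (45 comparisons per distance for the standard m = 10).
#'
#' @param scans list of at least 2 `distance_set` objects for one scanner with
#'   identical pair sets.
#' @return A long-format data.frame of accuracy records (`metric =
#'   "precision"`, `signed_error_um = NA`); `rep_index` identifies the scan
#'   pair as `"i-j"`.
#' @export
precision_errors <- function(scans) {
  if (length(scans) < 2L)
    scanmetry_error("precision needs at least 2 repeated scans",
                    "scanmetry_insufficient_replicates_error")
  p0 <- scans[[1L]]$pairs
  for (ds in scans[-1L]) check_pair_match(ds$pairs$pair, p0$pair, "repeated scans")
  m <- length(scans)
  # distances as a pairs x scans matrix, aligned on pair label
  D <- matrix(vapply(scans, function(ds)
    ds$pairs$distance_mm[match(p0$pair, ds$pairs$pair)], numeric(nrow(p0))),
    nrow = nrow(p0))
  cmb <- utils::combn(m, 2L)
  records <- lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1L, k]; j <- cmb[2L, k]
    data.frame(scanner_id = scans[[1L]]$scanner_id,
               metric = "precision",
               group = p0$group,
               pair = p0$pair,
               rep_index = sprintf("%d-%d", i, j),
               signed_error_um = NA_real_,
               abs_error_um = abs(D[, i] - D[, j]) * 1000)
  })
  do.call(rbind, records)
}

#' Descriptive summaries of accuracy records
#'
#' Median, interquartile range (Q3 - Q1, linearly interpolated quartiles,
#' quantile type 7), mean and sample standard deviation (n - 1 denominator) of
#' the absolute errors, per cell of the grouping. A single-observation cell
#' has no sample SD; it is reported as 0 with `degenerate_sd = TRUE` and a
#' warning.
#'
#' @param records accuracy-record data.frame
#'   ([trueness_errors()] / [precision_errors()] output, possibly rbind-ed).
#' @param by grouping columns; defaults to scanner, metric and distance group
#'   (columns absent from `records` are dropped).
#' @return data.frame with one row per cell: the grouping columns plus
#'   `median_um`, `iqr_um`, `mean_um`, `sd_um`, `n`, `degenerate_sd`.
#' @export
descriptive_stats <- function(records, by = c("scanner_id", "metric", "group")) {
  by <- intersect(by, names(records))
  if (!length(by) || !nrow(records))
    scanmetry_error("records empty or no grouping columns present",
                    "scanmetry_validation_error")
  key <- interaction(records[by], drop = FALSE, sep = "\r")
  cells <- split(seq_len(nrow(records)), key)
  empty <- vapply(cells, length, integer(1L)) == 0L
  if (any(empty)) {
    warning(sprintf("%d empty cell(s) omitted from descriptive summary", sum(empty)))
    cells <- cells[!empty]
  }
  rows <- lapply(names(cells), function(nm) {
    idx <- cells[[nm]]
    v <- records$abs_error_um[idx]
    n <- length(v)
    degenerate <- n < 2L
    if (degenerate)
      warning(sprintf("cell %s has a single observation; SD reported as 0",
                      gsub("\r", "/", nm)))
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    cbind(records[idx[1L], by, drop = FALSE],
          data.frame(median_um = stats::median(v),
                     iqr_um = q[2L] - q[1L],
                     mean_um = mean(v),
                     sd_um = if (degenerate) 0 else stats::sd(v),
                     n = n,
                     degenerate_sd = degenerate))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Maximum permissible length error of the reference CMM
#'
#' The coordinate measuring machine's certified maximum permissible length
#' error (E0, MPE) as a function of measured length:
#' MPE(L) = 3.5 um + L / 250, with L in mm and the result in micrometres.
#' Used to annotate reference distances with their uncertainty bound.
#'
#' @param L measured length(s) in mm, non-negative.
#' @return MPE in micrometres (vectorized over `L`).
#' @export
cmm_mpe <- function(L) {
  if (!is.numeric(L) || any(!is.finite(L)) || any(L < 0))
    scanmetry_error("L must be non-negative finite length(s) in mm",
                    "scanmetry_validation_error")
  3.5 + L / 250
}
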