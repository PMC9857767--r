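# ---- internal vector helpers -------------------------------------------------

unit_vec <- function(v) v / sqrt(sum(v^2))

# Orthonormal pair (e1, e2) completing unit vector d to a right-handed frame.
orthonormal_frame <- function(d) {
  a <- if (abs(d[1]) <= abs(d[2]) && abs(d[1]) <= abs(d[3])) c(1, 0, 0)
       else if (abs(d[2]) <= abs(d[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- unit_vec(a - sum(a * d) * d)
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

as_point_matrix <- function(points, what = "points") {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.list(points) && !is.matrix(points)) points <- do.call(rbind, points)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L)
    stop(errorCondition(sprintf("%s must be an n x 3 matrix of 3D coordinates", what),
                        class = c("scanmetry_validation_error", "error", "condition")))
  if (!all(is.finite(points)))
    stop(errorCondition(sprintf("%s contain non-finite coordinates", what),
                        class = c("scanmetry_validation_error", "error", "condition")))
  dimnames(points) <- NULL
  points
}

scanmetry_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "scanmetry_error", "error", "condition")))
}

# ---- contact point sets ------------------------------------------------------

#' Labeled contact points for one scan body
#'
#' Bundles the touch points probed on a scan body's cylindrical outer wall and
#' on its planar top face. These are the raw inputs of the geometric feature
#' fits: the cylinder points determine the body axis, the plane points the top
#' face, and their intersection the pierce-point centroid.
#'
#' @param body_id integer label of the scan body (bodies are numbered along the
#'   scan progression).
#' @param cylinder_points n x 3 matrix (mm) of points on the cylindrical wall;
#'   at least 6 are required (5 cylinder parameters plus one redundancy).
#' @param plane_points n x 3 matrix (mm) of points on the planar top face; at
#'   least 4 are required.
#' @return An object of class `contact_point_set`.
#' @export
contact_point_set <- function(body_id, cylinder_points, plane_points) {
  cylinder_points <- as_point_matrix(cylinder_points, "cylinder_points")
  plane_points <- as_point_matrix(plane_points, "plane_points")
  body_id <- as.integer(body_id)
  if (length(body_id) != 1L || is.na(body_id))
    scanmetry_error("body_id must be a single integer", "scanmetry_validation_error")
  if (nrow(cylinder_points) < 6L)
    scanmetry_error(sprintf("body %d: cylinder fitting needs at least 6 points, got %d",
                            body_id, nrow(cylinder_points)),
                    "scanmetry_insufficient_points_error")
  if (nrow(plane_points) < 4L)
    scanmetry_error(sprintf("body %d: plane fitting needs at least 4 points, got %d",
                            body_id, nrow(plane_points)),
                    "scanmetry_insufficient_points_error")
  structure(list(body_id = body_id,
                 cylinder_points = cylinder_points,
                 plane_points = plane_points),
            class = "contact_point_set")
}

#' @export
print.contact_point_set <- function(x, ...) {
  cat(sprintf("<contact_point_set> body %d: %d cylinder + %d plane points\n",
              x$body_id, nrow(x$cylinder_points), nrow(x$plane_points)))
  invisible(x)
}

# ---- plane fitting -----------------------------------------------------------

#' Total-least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared orthogonal point-to-plane
#' distances, via singular value decomposition of the centered point cloud
#' (the normal is the right singular vector of the smallest singular value;
#' equivalently the eigenvector of the smallest eigenvalue of the scatter
#' matrix). The normal is oriented so its dot product with +z is non-negative
#' (ties broken towards +x, then +y).
#'
#' @param points n x 3 matrix of 3D coordinates (mm), n >= 4, not collinear.
#' @return An object of class `plane_fit` with fields `point_on_plane` (the
#'   point-cloud centroid), `unit_normal`, `rms_residual` and `max_residual`
#'   (both mm).
#' @export
fit_plane <- function(points) {
  P <- as_point_matrix(points)
  if (nrow(P) < 4L)
    scanmetry_error(sprintf("plane fitting needs at least 4 points, got %d", nrow(P)),
                    "scanmetry_insufficient_points_error")
  ctr <- colMeans(P)
  M <- sweep(P, 2L, ctr)
  sv <- svd(M)
  # collinear or coincident points leave < 2 significant singular values
  if (sv$d[2] <= max(sv$d[1], .Machine$double.eps) * 1e-10)
    scanmetry_error("degenerate geometry: points are collinear or coincident",
                    "scanmetry_degenerate_geometry_error")
  n <- sv$v[, 3L]
  s <- n[3L]
  if (abs(s) < 1e-12) s <- n[1L]
  if (abs(s) < 1e-12) s <- n[2L]
  if (s < 0) n <- -n
  res <- drop(M %*% n)
  structure(list(point_on_plane = ctr,
                 unit_normal = n,
                 rms_residual = sqrt(mean(res^2)),
                 max_residual = max(abs(res))),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("<plane_fit> normal (%.6f, %.6f, %.6f), rms residual %.3g mm\n",
              x$unit_normal[1], x$unit_normal[2], x$unit_normal[3], x$rms_residual))
  invisible(x)
}

# ---- cylinder fitting --------------------------------------------------------

cylinder_residuals <- function(P, c0, d, r) {
  Q <- sweep(P, 2L, c0)
  t <- drop(Q %*% d)
  radial <- Q - tcrossprod(t, d)
  sqrt(rowSums(radial^2)) - r
}

#' Orthogonal least-squares cylinder fit
#'
#' Gauss-Newton minimization of the sum of squared orthogonal point-to-surface
#' distances, sum over i of (dist(p_i, axis) - r)^2. The axis point is gauged to
#' the plane through the point-cloud centroid orthogonal to the current axis,
#' leaving 5 effective parameters (2 axis-point offsets, 2 direction tilts, the
#' radius). Steps are damped by backtracking so the objective never increases;
#' the fit converges when the relative step norm drops below `tol`.
#'
#' If no initialization is given the axis direction starts at the
#' smallest-scatter principal direction of the points. For scan bodies whose
#' planar top face is orthogonal to the axis, pass the fitted plane normal as
#' `init = list(axis_direction = ...)` (this is what [extract_centroids()]
#' does).
#'
#' @param points n x 3 matrix (mm), n >= 6.
#' @param init optional list (or `cylinder_fit`) with any of `axis_direction`,
#'   `axis_point`, `radius` used to start the iteration.
#' @param tol relative step-norm convergence tolerance.
#' @param max_iter maximum Gauss-Newton iterations.
#' @return An object of class `cylinder_fit` with fields `axis_point`,
#'   `axis_direction` (unit, sign matching the initialization direction),
#'   `radius`, `rms_residual`, `objective`, `converged`, `iterations` and
#'   `n_points`. Non-convergence returns the best iterate with
#'   `converged = FALSE`, never silently.
#' @export
fit_cylinder <- function(points, init = NULL, tol = 1e-10, max_iter = 200L) {
  P <- as_point_matrix(points)
  n <- nrow(P)
  if (n < 6L)
    scanmetry_error(sprintf("cylinder fitting needs at least 6 points, got %d", n),
                    "scanmetry_insufficient_points_error")
  if (is.null(init) || is.null(init$axis_direction)) {
    # no caller-supplied axis: the principal directions are the natural
    # candidates, but which one is the axis depends on the point layout, so
    # fit from all three (smallest scatter first) and keep the best fit
    ev <- eigen(stats::cov(P), symmetric = TRUE)
    fits <- lapply(3:1, function(j) {
      cand <- init
      if (is.null(cand)) cand <- list()
      cand$axis_direction <- ev$vectors[, j]
      tryCatch(fit_cylinder(P, init = cand, tol = tol, max_iter = max_iter),
               scanmetry_error = function(e) NULL)
    })
    fits <- fits[!vapply(fits, is.null, logical(1L))]
    if (!length(fits))
      scanmetry_error("degenerate geometry: cylinder fit failed from every principal direction",
                      "scanmetry_degenerate_geometry_error")
    obj <- vapply(fits, function(f) f$objective, numeric(1L))
    conv <- vapply(fits, function(f) f$converged, logical(1L))
    ord <- order(obj, !conv)  # lowest objective wins; convergence breaks ties
    return(fits[[ord[1L]]])
  }
  few_points <- n < 8L
  ctr <- colMeans(P)

  d <- unit_vec(as.numeric(init$axis_direction))
  d0 <- d
  c0 <- if (!is.null(init) && !is.null(init$axis_point)) as.numeric(init$axis_point) else ctr
  c0 <- c0 - sum((c0 - ctr) * d) * d
  r <- if (!is.null(init) && !is.null(init$radius)) as.numeric(init$radius)
       else mean(sqrt(rowSums((sweep(P, 2L, c0) - tcrossprod(drop(sweep(P, 2L, c0) %*% d), d))^2)))
  if (!is.finite(r) || r <= .Machine$double.eps)
    scanmetry_error("degenerate geometry: points give a non-positive initial radius",
                    "scanmetry_degenerate_geometry_error")

  f0 <- cylinder_residuals(P, c0, d, r)
  obj <- sum(f0^2)
  converged <- FALSE
  iter <- 0L
  h <- 1e-7 * max(1, r)

  while (iter < max_iter) {
    iter <- iter + 1L
    fr <- orthonormal_frame(d)
    apply_step <- function(p) {
      dd <- unit_vec(d + p[3L] * fr$e1 + p[4L] * fr$e2)
      cc <- c0 + p[1L] * fr$e1 + p[2L] * fr$e2
      cc <- cc - sum((cc - ctr) * dd) * dd
      list(c0 = cc, d = dd, r = r + p[5L])
    }
    J <- matrix(0, n, 5L)
    for (j in 1:5) {
      p <- numeric(5L); p[j] <- h
      st <- apply_step(p)
      J[, j] <- (cylinder_residuals(P, st$c0, st$d, st$r) - f0) / h
    }
    delta <- tryCatch(qr.solve(J, -f0), error = function(e) NULL)
    if (is.null(delta)) {
      # Gauss-Newton normal equations singular: Levenberg fallback
      A <- crossprod(J) + diag(1e-8 * max(diag(crossprod(J)), 1), 5L)
      delta <- drop(solve(A, -crossprod(J, f0)))
    }
    rel_step <- sqrt(sum(delta^2)) / (1 + abs(r))
    if (rel_step < tol) { converged <- TRUE; break }

    lam <- 1
    improved <- FALSE
    for (k in 1:30) {
      st <- apply_step(lam * delta)
      if (st$r > .Machine$double.eps) {
        fc <- cylinder_residuals(P, st$c0, st$d, st$r)
        oc <- sum(fc^2)
        if (oc < obj) {
          c0 <- st$c0; d <- st$d; r <- st$r; f0 <- fc; obj <- oc
          improved <- TRUE
          rel_step <- sqrt(sum((lam * delta)^2)) / (1 + abs(r))
          break
        }
      }
      lam <- lam / 2
    }
    if (!improved) {
      # the line search halved the step to nothing without lowering the
      # objective: the iterate is a numerical stationary point, and the
      # accepted step (zero) is below tolerance
      converged <- TRUE
      break
    }
    if (rel_step < tol) { converged <- TRUE; break }
  }

  if (r <= 0)
    scanmetry_error("degenerate geometry: cylinder radius collapsed to <= 0",
                    "scanmetry_degenerate_geometry_error")
  if (sum(d * d0) < 0) d <- -d
  structure(list(axis_point = c0,
                 axis_direction = d,
                 radius = r,
                 rms_residual = sqrt(obj / n),
                 objective = obj,
                 converged = converged,
                 iterations = iter,
                 n_points = n,
                 few_points = few_points),
            class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf("<cylinder_fit> radius %.6f mm, axis (%.6f, %.6f, %.6f)\n",
              x$radius, x$axis_direction[1], x$axis_direction[2], x$axis_direction[3]))
  cat(sprintf("  rms residual %.3g mm, %d iterations, converged: %s%s\n",
              x$rms_residual, x$iterations, x$converged,
              if (isTRUE(x$few_points)) " (fitted from fewer than 8 points)" else ""))
  invisible(x)
}

# ---- pierce point ------------------------------------------------------------

#' Pierce-point centroid of a scan body
#'
#' Intersects the fitted cylinder axis with the fitted top plane. The unique
#' point p = axis_point + t * axis_direction with
#' (p - point_on_plane) . unit_normal = 0 is the scan body's canonical
#' landmark ("centroid"), the unit of all downstream distance measurement.
#'
#' @param cyl a `cylinder_fit`.
#' @param plane a `plane_fit`.
#' @param body_id integer label carried onto the centroid.
#' @return An object of class `centroid` with fields `body_id`, `x`, `y`, `z`
#'   (mm).
#' @export
pierce_point <- function(cyl, plane, body_id = NA_integer_) {
  d <- cyl$axis_direction
  nrm <- plane$unit_normal
  dn <- sum(d * nrm)
  if (abs(dn) <= 1e-6)
    scanmetry_error("cylinder axis is (near-)parallel to the plane: no intersection",
                    "scanmetry_no_intersection_error")
  t <- sum((plane$point_on_plane - cyl$axis_point) * nrm) / dn
  p <- cyl$axis_point + t * d
  structure(list(body_id = as.integer(body_id), x = p[1L], y = p[2L], z = p[3L]),
            class = "centroid")
}

#' @export
print.centroid <- function(x, ...) {
  cat(sprintf("<centroid> body %s: (%.6f, %.6f, %.6f) mm\n",
              x$body_id, x$x, x$y, x$z))
  invisible(x)
}

centroid_coords <- function(centroids) {
  m <- t(vapply(centroids, function(ct) c(ct$x, ct$y, ct$z), numeric(3L)))
  rownames(m) <- vapply(centroids, function(ct) as.character(ct$body_id), character(1L))
  m
}
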