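# STL (Standard Tessellation Language) mesh support: triangle meshes of the
# idealized scan bodies, a binary/ASCII writer and a reader for both dialects.
# Binary STL: 80-byte header, uint32 facet count, then per facet 12 float32
# (normal + 3 vertices) and a 2-byte attribute, all little-endian.

#' Triangle mesh of one scan body
#'
#' Tessellates the idealized scan body (cylinder wall plus top and bottom
#' discs) with `segments` angular segments (default 64, so the chord sagitta
#' is bounded by r * (1 - cos(pi/segments))).
#'
#' @param body per-body geometry (fields `base`, `axis`, `radius`,
#'   `top_offset`).
#' @param segments angular tessellation segments.
#' @return List with `vertices` (V x 3) and `faces` (F x 3 vertex indices).
#' @export
scan_body_mesh <- function(body, segments = 64L) {
  fr <- orthonormal_frame(body$axis)
  ang <- 2 * pi * (seq_len(segments) - 1) / segments
  ring <- function(height)
    t(vapply(ang, function(a)
      body$base + body$radius * (cos(a) * fr$e1 + sin(a) * fr$e2) + height * body$axis,
      numeric(3L)))
  bot <- ring(0)
  top <- ring(body$top_offset)
  c_bot <- body$base
  c_top <- body$base + body$top_offset * body$axis
  vertices <- rbind(bot, top, c_bot, c_top)
  i <- seq_len(segments)
  j <- c(seq_len(segments)[-1L], 1L)             # next vertex around the ring
  wall <- rbind(cbind(i, j, segments + i),
                cbind(j, segments + j, segments + i))
  bottom <- cbind(j, i, 2L * segments + 1L)       # wound to face -axis
  topcap <- cbind(segments + i, segments + j, 2L * segments + 2L)
  list(vertices = vertices, faces = rbind(wall, bottom, topcap))
}

#' Combined mesh of a whole scan
#'
#' @param bodies list of per-body geometries (e.g. the `bodies` attribute of a
#'   simulated scan, or a `master_geometry`'s `bodies`).
#' @param segments angular tessellation segments per body.
#' @return List with `vertices` and `faces` covering all bodies.
#' @export
scan_mesh <- function(bodies, segments = 64L) {
  offset <- 0L
  vs <- list(); fs <- list()
  for (b in bodies) {
    m <- scan_body_mesh(b, segments)
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + offset
    offset <- offset + nrow(m$vertices)
  }
  list(vertices = do.call(rbind, vs), faces = do.call(rbind, fs))
}

facet_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  u <- vertices[faces[, 2L], , drop = FALSE] - a
  v <- vertices[faces[, 3L], , drop = FALSE] - a
  n <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
             u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
             u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Write a triangle mesh as STL
#'
#' Binary (default; little-endian, 80-byte header) or ASCII. Per-facet normals
#' are recomputed from the vertex winding.
#'
#' @param mesh list with `vertices` (V x 3) and `faces` (F x 3).
#' @param path output file.
#' @param format `"binary"` or `"ascii"`.
#' @param solid_name solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii"),
                      solid_name = "scanmetry") {
  format <- match.arg(format)
  V <- mesh$vertices; f <- mesh$faces
  nf <- nrow(f)
  nrm <- facet_normals(V, f)
  tri <- cbind(nrm, V[f[, 1L], , drop = FALSE], V[f[, 2L], , drop = FALSE],
               V[f[, 3L], , drop = FALSE])  # nf x 12
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("scanmetry binary STL:", solid_name)))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    fl <- writeBin(as.numeric(t(tri)), raw(), size = 4L, endian = "little")
    m <- matrix(fl, nrow = 48L)                     # one facet per column
    block <- rbind(m, matrix(as.raw(0L), 2L, nf))   # 2-byte attribute count
    writeBin(as.vector(block), con)
  } else {
    fmt <- paste0("  facet normal %.9e %.9e %.9e\n    outer loop\n",
                  "      vertex %.9e %.9e %.9e\n      vertex %.9e %.9e %.9e\n",
                  "      vertex %.9e %.9e %.9e\n    endloop\n  endfacet")
    lines <- c(sprintf("solid %s", solid_name),
               sprintf(fmt, tri[, 1L], tri[, 2L], tri[, 3L], tri[, 4L], tri[, 5L],
                       tri[, 6L], tri[, 7L], tri[, 8L], tri[, 9L], tri[, 10L],
                       tri[, 11L], tri[, 12L]),
               sprintf("endsolid %s", solid_name))
    writeLines(lines, path)
  }
  invisible(path)
}

stl_format_error <- function(msg, offset = NA) {
  scanmetry_error(if (is.na(offset)) msg
                  else sprintf("%s (at byte offset %d)", msg, offset),
                  "scanmetry_stl_format_error")
}

#' Read an STL file
#'
#' Parses both binary and ASCII STL (auto-detected: a file whose size matches
#' the binary facet count is binary, regardless of a leading "solid").
#' Vertices are returned as read, three per facet, without deduplication
#' unless `dedupe = TRUE`.
#'
#' @param path STL file.
#' @param dedupe merge bitwise-identical vertices.
#' @return List with `vertices`, `faces`, `normals` (as stored in the file),
#'   `n_vertices`, `n_facets`.
#' @export
read_stl <- function(path, dedupe = FALSE) {
  if (!file.exists(path))
    scanmetry_error(sprintf("file not found: %s", path), "scanmetry_validation_error")
  sz <- file.size(path)
  is_binary <- FALSE
  if (sz >= 84) {
    con <- file(path, "rb")
    invisible(readBin(con, raw(), 80L))
    nf <- readBin(con, integer(), 1L, size = 4L, endian = "little")
    close(con)
    if (!is.na(nf) && nf >= 0 && sz == 84 + 50 * nf) is_binary <- TRUE
  }
  if (is_binary) {
    raw_all <- readBin(path, raw(), sz)
    nf <- readBin(raw_all[81:84], integer(), 1L, size = 4L, endian = "little")
    body <- raw_all[-(1:84)]
    if (length(body) != 50L * nf)
      stl_format_error("truncated binary STL facet data", 84 + length(body))
    m <- matrix(body, nrow = 50L)
    vals <- readBin(as.vector(m[1:48, , drop = FALSE]), numeric(),
                    n = 12L * nf, size = 4L, endian = "little")
    arr <- matrix(vals, ncol = 12L, byrow = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !grepl("^\\s*solid", lines[1L]))
      stl_format_error("malformed STL header: neither valid binary nor ASCII 'solid'", 0)
    vtx_lines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    nrm_lines <- grep("^\\s*facet\\s+normal\\s", lines, value = TRUE)
    if (length(vtx_lines) %% 3L != 0L || length(vtx_lines) != 3L * length(nrm_lines))
      stl_format_error(sprintf(
        "truncated ASCII STL: %d facets but %d vertex lines",
        length(nrm_lines), length(vtx_lines)))
    num3 <- function(x, drop_first)
      t(vapply(strsplit(trimws(x), "\\s+"), function(p)
        as.numeric(p[drop_first + (1:3)]), numeric(3L)))
    vm <- num3(vtx_lines, 1L)
    nm <- num3(nrm_lines, 2L)
    nf <- length(nrm_lines)
    arr <- cbind(nm,
                 vm[seq(1L, 3L * nf, by = 3L), , drop = FALSE],
                 vm[seq(2L, 3L * nf, by = 3L), , drop = FALSE],
                 vm[seq(3L, 3L * nf, by = 3L), , drop = FALSE])
  }
  normals <- arr[, 1:3, drop = FALSE]
  vertices <- matrix(NA_real_, 3L * nf, 3L)
  vertices[seq(1L, 3L * nf, by = 3L), ] <- arr[, 4:6, drop = FALSE]
  vertices[seq(2L, 3L * nf, by = 3L), ] <- arr[, 7:9, drop = FALSE]
  vertices[seq(3L, 3L * nf, by = 3L), ] <- arr[, 10:12, drop = FALSE]
  faces <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  if (dedupe) {
    key <- paste(format(vertices[, 1L], digits = 17),
                 format(vertices[, 2L], digits = 17),
                 format(vertices[, 3L], digits = 17))
    uk <- !duplicated(key)
    map <- match(key, key[uk])
    vertices <- vertices[uk, , drop = FALSE]
    faces <- matrix(map[faces], ncol = 3L)
  }
  list(vertices = vertices, faces = faces, normals = normals,
       n_vertices = nrow(vertices), n_facets = nf)
}
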