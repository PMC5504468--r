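#' Triangulated surface mesh
#'
#' A minimal container for closed head/brain surfaces in AC-PC millimetre
#' coordinates: an n x 3 vertex matrix and an m x 3 face matrix of 1-based
#' vertex indices. Faces with (numerically) zero area are rejected because
#' downstream plane sections and ray casts assume non-degenerate triangles.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and a logical `watertight` flag (every edge shared by exactly
#'   two faces).
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) < 1L) stop("mesh needs at least one face")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c3 <- vertices[faces[, 3L], , drop = FALSE]
  cr <- cross3(b - a, c3 - a)
  area2 <- sqrt(rowSums(cr * cr))
  scale <- max(1, max(abs(vertices)))
  if (any(area2 <= 1e-12 * scale^2))
    stop("mesh contains degenerate (zero-area) triangles")
  structure(
    list(vertices = vertices, faces = faces,
         watertight = is_watertight(faces)),
    class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(x$watertight)) "watertight" else "open"))
  invisible(x)
}

# every undirected edge must appear in exactly two faces
is_watertight <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(tabulate(factor(key)) == 2L)
}

# row-wise cross product of n x 3 matrices
cross3 <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

#' Median edge length of a mesh
#'
#' Used as the resolution scale for arc-endpoint snapping tolerances.
#' @param mesh a [triangle_mesh()].
#' @return median edge length in mm.
#' @export
median_edge_length <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  e <- rbind(v[f[, 1L], ] - v[f[, 2L], ],
             v[f[, 2L], ] - v[f[, 3L], ],
             v[f[, 3L], ] - v[f[, 1L], ])
  stats::median(sqrt(rowSums(e * e)))
}

#' Closest point on a mesh surface
#'
#' Exact closest point over all triangles (Ericson's region test,
#' vectorized over faces). Serves point-on-surface validation and the
#' nearest-surface fallback of [adjust_to_surface()].
#'
#' @param mesh a [triangle_mesh()].
#' @param p numeric length-3 point (mm).
#' @return list with `point` (length-3), `distance` (mm) and `face` index.
#' @export
closest_point_on_mesh <- function(mesh, p) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  pm <- matrix(p, nrow(f), 3L, byrow = TRUE)

  ab <- b - a; ac <- c3 - a; ap <- pm - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- pm - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- pm - c3
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)

  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  out <- a  # region A default
  # region B
  i <- d3 >= 0 & d4 <= d3
  out[i, ] <- b[i, ]
  # region C
  i <- d6 >= 0 & d5 <= d6
  out[i, ] <- c3[i, ]
  # edge AB
  i <- vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(i)) {
    t <- d1[i] / (d1[i] - d3[i])
    out[i, ] <- a[i, , drop = FALSE] + t * ab[i, , drop = FALSE]
  }
  # edge AC
  i <- vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(i)) {
    t <- d2[i] / (d2[i] - d6[i])
    out[i, ] <- a[i, , drop = FALSE] + t * ac[i, , drop = FALSE]
  }
  # edge BC
  i <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(i)) {
    t <- (d4[i] - d3[i]) / ((d4[i] - d3[i]) + (d5[i] - d6[i]))
    out[i, ] <- b[i, , drop = FALSE] +
      t * (c3[i, , drop = FALSE] - b[i, , drop = FALSE])
  }
  # interior
  denom <- va + vb + vc
  i <- vc > 0 & vb > 0 & va > 0 & d1 > 0 & d2 > 0 &
    !(d3 >= 0 & d4 <= d3) & !(d6 >= 0 & d5 <= d6)
  # interior test via barycentric positivity (guarded against denom ~ 0)
  i <- i & denom > 1e-300
  if (any(i)) {
    w <- vb[i] / denom[i]
    u <- vc[i] / denom[i]
    out[i, ] <- a[i, , drop = FALSE] + w * ab[i, , drop = FALSE] +
      u * ac[i, , drop = FALSE]
  }
  d <- sqrt(rowSums((out - pm)^2))
  j <- which.min(d)
  list(point = out[j, ], distance = d[j], face = j)
}

#' Distance from a point to the mesh surface
#' @inheritParams closest_point_on_mesh
#' @return distance in mm.
#' @export
surface_distance <- function(mesh, p) closest_point_on_mesh(mesh, p)$distance

#' Read a triangulated mesh from an ASCII OBJ or PLY file
#'
#' Only the geometry is read (`v`/`f` records for OBJ; ASCII `ply` with
#' vertex x/y/z properties and triangular faces). Units are taken as mm and
#' no transform is applied.
#'
#' @param path file path; format chosen from the extension (.obj/.ply).
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path),
         ply = read_ply(path),
         stop("unsupported mesh format: ", ext))
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                                 function(x) {
                                   idx <- as.integer(sub("/.*$", "", x))
                                   if (length(idx) != 3L)
                                     stop("only triangular faces are supported")
                                   idx
                                 }))
  triangle_mesh(verts, faces)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(trimws(lines[1L]), "ply")) stop("not a PLY file")
  endh <- match("end_header", trimws(lines))
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", header)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1L]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1L]))
  body <- lines[(endh + 1L):length(lines)]
  vt <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                              function(x) as.numeric(x[1:3])))
  ft <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                              function(x) {
                                x <- as.integer(x)
                                if (x[1L] != 3L)
                                  stop("only triangular faces are supported")
                                x[2:4] + 1L
                              }))
  triangle_mesh(vt, ft)
}

#' Write a mesh to ASCII OBJ or PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path destination; format chosen from the extension (.obj/.ply).
#' @param digits coordinate precision (decimal digits).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, digits = 6L) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  fmt <- paste0("%.", digits, "f")
  if (ext == "obj") {
    lines <- c(sprintf(paste("v", fmt, fmt, fmt), v[, 1L], v[, 2L], v[, 3L]),
               sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]))
  } else if (ext == "ply") {
    lines <- c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header",
               sprintf(paste(fmt, fmt, fmt), v[, 1L], v[, 2L], v[, 3L]),
               sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L))
  } else stop("unsupported mesh format: ", ext)
  writeLines(lines, path)
  invisible(path)
}

# UV-sphere triangulation of the unit sphere; directions later mapped through
# a radial scale to produce head/brain surfaces. Closed (watertight) by
# construction.
unit_sphere_mesh <- function(n_theta = 72L, n_phi = 36L) {
  phi <- seq(0, pi, length.out = n_phi + 1L)[-c(1L, n_phi + 1L)]
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  g <- expand.grid(theta = theta, phi = phi)
  verts <- rbind(c(0, 0, 1),
                 cbind(sin(g$phi) * cos(g$theta),
                       sin(g$phi) * sin(g$theta),
                       cos(g$phi)),
                 c(0, 0, -1))
  idx <- function(i, j) 1L + (i - 1L) * n_theta + j  # ring i (1..n_phi-1), col j
  south <- nrow(verts)
  faces <- vector("list", 3L)
  j2 <- c(2:n_theta, 1L)
  # top cap
  faces[[1L]] <- cbind(1L, idx(1L, 1:n_theta), idx(1L, j2))
  # bands
  if (n_phi > 2L) {
    band <- lapply(seq_len(n_phi - 2L), function(i) {
      a <- idx(i, 1:n_theta); b <- idx(i, j2)
      c3 <- idx(i + 1L, 1:n_theta); d <- idx(i + 1L, j2)
      rbind(cbind(a, c3, d), cbind(a, d, b))
    })
    faces[[2L]] <- do.call(rbind, band)
  }
  # bottom cap
  faces[[3L]] <- cbind(south, idx(n_phi - 1L, j2), idx(n_phi - 1L, 1:n_theta))
  triangle_mesh(verts, do.call(rbind, faces))
}
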