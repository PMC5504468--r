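#' Rigid alignment to the AC-PC frame
#'
#' Builds the stereotactic frame used throughout: origin at the AC-PC
#' midpoint, +y along PC->AC (posterior to anterior), +z in the midsagittal
#' plane towards the given superior midline point, +x left to right. The
#' transform is rigid (proper rotation + translation).
#'
#' @param points n x 3 matrix of points to transform (mm), or NULL.
#' @param ac,pc anterior / posterior commissure positions (length-3, mm).
#' @param mid_sagittal any midsagittal point clearly off the AC-PC line,
#'   superior to it (e.g. the vertex).
#' @return list of class `acpc_transform`: `rotation` (3 x 3, det +1),
#'   `origin` (length-3), and `points` (the transformed input, if given).
#'   Apply to new data with [apply_acpc()].
#' @examples
#' tr <- acpc_align(NULL, ac = c(10, 0, 0), pc = c(-10, 0, 0),
#'                  mid_sagittal = c(0, 0, 50))
#' apply_acpc(tr, c(10, 0, 0))  # -> (0, 10, 0)
#' @export
acpc_align <- function(points, ac, pc, mid_sagittal) {
  ac <- as.numeric(ac); pc <- as.numeric(pc)
  mid_sagittal <- as.numeric(mid_sagittal)
  axis <- ac - pc
  if (vnorm(axis) < 1e-9) stop("degenerate frame: AC and PC coincide")
  yhat <- axis / vnorm(axis)
  origin <- (ac + pc) / 2
  w <- mid_sagittal - origin
  w <- w - sum(w * yhat) * yhat
  if (vnorm(w) < 1e-9)
    stop("degenerate frame: midsagittal point lies on the AC-PC line")
  zhat <- w / vnorm(w)
  xhat <- c(yhat[2L] * zhat[3L] - yhat[3L] * zhat[2L],
            yhat[3L] * zhat[1L] - yhat[1L] * zhat[3L],
            yhat[1L] * zhat[2L] - yhat[2L] * zhat[1L])
  rot <- rbind(xhat, yhat, zhat)
  dimnames(rot) <- NULL
  out <- structure(list(rotation = rot, origin = origin), class = "acpc_transform")
  if (!is.null(points)) out$points <- apply_acpc(out, points)
  out
}

#' Apply an AC-PC transform to points
#' @param transform result of [acpc_align()].
#' @param points length-3 vector or n x 3 matrix.
#' @return transformed points, same shape as the input.
#' @export
apply_acpc <- function(transform, points) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1L, 3L) else as.matrix(points)
  out <- sweep(p, 2L, transform$origin) %*% t(transform$rotation)
  if (single) drop(out) else out
}

#' Section a mesh with a plane and extract the arc between two anchors
#'
#' Intersects the mesh with the plane through `a`, `b` and `third`, chains
#' the per-triangle intersection segments into polylines, and returns the
#' sub-arc running from `a` to `b` on the side of the section passing
#' nearest `third`. This is the curve primitive of the virtual 10-20/10-10
#' construction: `third` disambiguates "over-the-top" arcs (e.g. the
#' midline curve from nasion to inion passing through the vertex).
#'
#' @param mesh a [triangle_mesh()].
#' @param a,b arc endpoints (length-3, mm), on or near the surface.
#' @param third a non-collinear point selecting the plane and the sub-arc.
#' @param snap_tol endpoint snap tolerance in mm; defaults to half the
#'   median edge length.
#' @return object of class `surface_arc`: `polyline` (p x 3),
#'   `cumulative_length` (mm, starting at 0), `endpoints` (2 x 3).
#' @export
plane_section_arc <- function(mesh, a, b, third,
                              snap_tol = median_edge_length(mesh) / 2) {
  a <- as.numeric(a); b <- as.numeric(b); third <- as.numeric(third)
  if (vnorm(b - a) < 1e-9) stop("zero-length arc: endpoints coincide")
  n <- cross3(matrix(b - a, 1L), matrix(third - a, 1L))[1L, ]
  if (vnorm(n) < 1e-9 * max(vnorm(b - a), 1))
    stop("degenerate plane: a, b and third are collinear")
  n <- n / vnorm(n)
  loops <- section_polylines(mesh, n, sum(n * a))
  if (length(loops) == 0L) stop("plane does not intersect the mesh")

  # pick the section component nearest both anchors
  da <- vapply(loops, function(L) min_dist_to_polyline(L$pts, a)$dist, 0)
  db <- vapply(loops, function(L) min_dist_to_polyline(L$pts, b)$dist, 0)
  keep <- which(da <= snap_tol & db <= snap_tol)
  if (length(keep) == 0L) {
    i <- which.min(da + db)
    if (da[i] > snap_tol || db[i] > snap_tol)
      stop(sprintf(paste0("anchors not on one section component ",
                          "(snap distances %.3f / %.3f mm, tolerance %.3f mm)"),
                   da[i], db[i], snap_tol))
    keep <- i
  }
  L <- loops[[keep[which.min((da + db)[keep])]]]

  sub <- split_at_anchors(L, a, b)
  cands <- sub$arcs
  if (length(cands) > 1L) {
    dthird <- vapply(cands, function(P) min_dist_to_polyline(P, third)$dist, 0)
    pick <- cands[[which.min(dthird)]]
  } else pick <- cands[[1L]]
  make_surface_arc(pick)
}

# mesh-plane section as a list of chained polylines (closed loops carry
# closed=TRUE and do not repeat the first point). Intersection points are
# keyed by the crossed mesh edge, so segments from adjacent triangles share
# endpoints exactly and chaining needs no coordinate hashing.
section_polylines <- function(mesh, normal, offset) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.numeric(v %*% normal) - offset
  scale <- max(abs(d), 1e-9)
  d[abs(d) < 1e-12 * scale] <- 1e-12 * scale  # nudge on-plane vertices
  s <- d > 0
  sf <- cbind(s[f[, 1L]], s[f[, 2L]], s[f[, 3L]])
  nhit <- rowSums(sf)
  hit <- which(nhit %in% c(1L, 2L))
  if (length(hit) == 0L) return(list())

  edge_pairs <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  keys <- matrix(NA_character_, length(hit), 2L)
  for (e in 1:3) {
    i <- f[hit, edge_pairs[e, 1L]]
    j <- f[hit, edge_pairs[e, 2L]]
    crossed <- s[i] != s[j]
    if (!any(crossed)) next
    k <- paste(pmin(i, j), pmax(i, j))[crossed]
    rowidx <- which(crossed)
    slot <- ifelse(is.na(keys[rowidx, 1L]), 1L, 2L)
    keys[cbind(rowidx, slot)] <- k
  }
  stopifnot(!anyNA(keys))

  all_keys <- unique(as.vector(keys))
  key_id <- matrix(match(keys, all_keys), ncol = 2L)
  # one interpolated point per crossed edge
  ij <- do.call(rbind, strsplit(all_keys, " "))
  ii <- as.integer(ij[, 1L]); jj <- as.integer(ij[, 2L])
  t <- d[ii] / (d[ii] - d[jj])
  key_pt <- v[ii, , drop = FALSE] + t * (v[jj, , drop = FALSE] - v[ii, , drop = FALSE])

  # each crossed edge belongs to <= 2 hit faces
  edge_faces <- vector("list", length(all_keys))
  for (r in seq_along(hit)) {
    for (cidx in 1:2) {
      k <- key_id[r, cidx]
      edge_faces[[k]] <- c(edge_faces[[k]], r)
    }
  }

  used <- logical(length(hit))
  # walk from face r through its key k onwards; returns the key sequence
  walk <- function(r, k) {
    out <- integer(0)
    repeat {
      nb <- edge_faces[[k]]
      nb <- nb[nb != r & !used[nb]]
      if (length(nb) == 0L) break
      r <- nb[1L]
      used[r] <<- TRUE
      k <- if (key_id[r, 1L] == k) key_id[r, 2L] else key_id[r, 1L]
      out <- c(out, k)
    }
    out
  }
  loops <- list()
  for (r0 in seq_along(hit)) {
    if (used[r0]) next
    used[r0] <- TRUE
    k1 <- key_id[r0, 1L]; k2 <- key_id[r0, 2L]
    right <- walk(r0, k2)
    left <- walk(r0, k1)
    seqk <- c(rev(left), k1, k2, right)
    closed <- FALSE
    if (length(seqk) >= 3L && seqk[1L] == seqk[length(seqk)]) {
      seqk <- seqk[-length(seqk)]
      closed <- TRUE
    } else if (length(seqk) >= 3L) {
      # loop closure where both walks ended on a shared edge
      last <- seqk[length(seqk)]; first <- seqk[1L]
      fl <- edge_faces[[last]]; ff <- edge_faces[[first]]
      if (length(intersect(fl, ff)) > 0L && last != first) closed <- FALSE
    }
    loops[[length(loops) + 1L]] <-
      list(pts = key_pt[seqk, , drop = FALSE], closed = closed)
  }
  loops
}

# min distance from point to a polyline (open); returns distance and the
# arc-length position of the projection
min_dist_to_polyline <- function(P, x, closed = FALSE) {
  if (closed) P <- rbind(P, P[1L, ])
  A <- P[-nrow(P), , drop = FALSE]
  B <- P[-1L, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB * AB)
  len2[len2 < 1e-300] <- 1e-300
  t <- rowSums(sweep(A, 2L, x, "-") * -AB) / len2
  t <- pmin(1, pmax(0, t))
  proj <- A + t * AB
  d <- sqrt(rowSums(sweep(proj, 2L, x, "-")^2))
  i <- which.min(d)
  seglen <- sqrt(rowSums(AB * AB))
  s <- c(0, cumsum(seglen))[i] + t[i] * seglen[i]
  list(dist = d[i], s = s, point = proj[i, ], segment = i, t = t[i])
}

# split a section component at the projections of anchors a and b; returns
# candidate polylines from a to b (two for closed loops, one for open chains)
split_at_anchors <- function(L, a, b) {
  P <- L$pts
  if (L$closed) {
    Pc <- rbind(P, P[1L, ])
    pa <- min_dist_to_polyline(P, a, closed = TRUE)
    pb <- min_dist_to_polyline(P, b, closed = TRUE)
    total <- sum(sqrt(rowSums(diff(Pc)^2)))
    seglen <- sqrt(rowSums(diff(Pc)^2))
    cum <- c(0, cumsum(seglen))
    extract <- function(s0, s1) {
      # walk forward from arclength s0 to s1, wrapping around the loop
      if (s1 <= s0) s1 <- s1 + total
      sv <- c(cum[seq_len(nrow(P))], cum[seq_len(nrow(P))] + total)
      inner <- which(sv > s0 & sv < s1)
      innerw <- ((inner - 1L) %% nrow(P)) + 1L
      rbind(point_at_s(Pc, cum, s0 %% total),
            P[innerw, , drop = FALSE],
            point_at_s(Pc, cum, s1 %% total))
    }
    arc1 <- extract(pa$s, pb$s)
    arc2 <- extract(pb$s, pa$s)
    arc2 <- arc2[rev(seq_len(nrow(arc2))), , drop = FALSE]
    list(arcs = list(dedupe(arc1), dedupe(arc2)))
  } else {
    pa <- min_dist_to_polyline(P, a)
    pb <- min_dist_to_polyline(P, b)
    seglen <- sqrt(rowSums(diff(P)^2))
    cum <- c(0, cumsum(seglen))
    s0 <- min(pa$s, pb$s); s1 <- max(pa$s, pb$s)
    inner <- which(cum > s0 & cum < s1)
    pts <- rbind(point_at_s(P, cum, s0),
                 P[inner, , drop = FALSE],
                 point_at_s(P, cum, s1))
    if (pa$s > pb$s) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    list(arcs = list(dedupe(pts)))
  }
}

point_at_s <- function(P, cum, s) {
  s <- max(0, min(s, cum[length(cum)]))
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- max(1L, min(i, nrow(P) - 1L))
  t <- (s - cum[i]) / max(cum[i + 1L] - cum[i], 1e-300)
  P[i, ] + t * (P[i + 1L, ] - P[i, ])
}

dedupe <- function(P, tol = 1e-9) {
  if (nrow(P) < 2L) return(P)
  keep <- c(TRUE, sqrt(rowSums(diff(P)^2)) > tol)
  P[keep, , drop = FALSE]
}

make_surface_arc <- function(P) {
  if (nrow(P) < 2L) stop("arc degenerated to a point")
  seglen <- sqrt(rowSums(diff(P)^2))
  structure(list(polyline = P,
                 cumulative_length = c(0, cumsum(seglen)),
                 endpoints = P[c(1L, nrow(P)), , drop = FALSE]),
            class = "surface_arc")
}

#' Arc length of a surface arc
#' @param arc a `surface_arc`.
#' @return total length in mm.
#' @export
arc_length <- function(arc) {
  arc$cumulative_length[length(arc$cumulative_length)]
}

#' Point at a fractional arc length along a surface arc
#'
#' The 10% (and 5%) subdivision primitive of the virtual 10-20/10-10
#' construction: linear interpolation along the section polyline at the
#' requested fraction of total length.
#'
#' @param arc a `surface_arc` from [plane_section_arc()].
#' @param f fraction in \[0, 1\] of total arc length from the start point.
#' @return length-3 point (mm).
#' @export
point_at_fraction <- function(arc, f) {
  if (length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    stop("fraction must be a single value in [0, 1]")
  cum <- arc$cumulative_length
  point_at_s(arc$polyline, cum, f * cum[length(cum)])
}

#' Outermost ray-mesh intersection
#'
#' Casts a ray and returns the intersection with the largest positive ray
#' parameter — the outermost scalp crossing, as used by scalp projection
#' and back-projection. Vectorized Moller-Trumbore over all faces.
#'
#' @param mesh a [triangle_mesh()].
#' @param origin ray origin (length-3, mm).
#' @param direction ray direction (length-3, any nonzero length).
#' @return list: `point` (length-3), `t` (distance along the unit-length
#'   direction, mm), `face` (index).
#' @export
ray_surface_intersection <- function(mesh, origin, direction) {
  direction <- as.numeric(direction)
  if (vnorm(direction) < 1e-12) stop("ray direction must be nonzero")
  dirn <- direction / vnorm(direction)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  dmat <- matrix(dirn, nrow(f), 3L, byrow = TRUE)
  h <- cross3(dmat, e2)
  det <- rowSums(e1 * h)
  ok <- abs(det) > 1e-12
  tvec <- sweep(a, 2L, origin, "-") * -1  # origin - a
  u <- rowSums(tvec * h) / det
  q <- cross3(tvec, e1)
  vv <- rowSums(dmat * q) / det
  tt <- rowSums(e2 * q) / det
  eps <- 1e-9
  hitok <- ok & u >= -eps & vv >= -eps & (u + vv) <= 1 + eps & tt > 1e-9
  if (!any(hitok)) stop("ray misses the mesh")
  i <- which(hitok)[which.max(tt[hitok])]
  list(point = origin + tt[i] * dirn, t = tt[i], face = i)
}

#' Project points onto the sagittal or coronal plane
#'
#' Sagittal projection zeroes x (used for medial structures); coronal
#' projection zeroes y (used for height analyses). Other coordinates are
#' unchanged.
#'
#' @param points length-3 vector or n x 3 matrix (mm).
#' @param plane `"sagittal"` or `"coronal"`.
#' @return projected points, same shape as the input.
#' @export
project <- function(points, plane = c("sagittal", "coronal")) {
  plane <- match.arg(plane)
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1L, 3L) else as.matrix(points)
  p[, if (plane == "sagittal") 1L else 2L] <- 0
  if (single) drop(p) else p
}
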