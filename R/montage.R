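#' Iterative vertex (Cz) placement from the four cranial fiducials
#'
#' Alternating construction: Cz is the point that is simultaneously the 50%
#' point of the surface arc Nz-Cz-Iz and of the arc AL-Cz-AR. Starting from
#' the topmost mesh vertex, each iteration re-slices both arcs through the
#' current Cz estimate and moves Cz to the midpoint, until the move falls
#' below `tol`.
#'
#' @param mesh scalp [triangle_mesh()].
#' @param fiducials 4 x 3 matrix with rows `Nz`, `Iz`, `AL`, `AR` (mm),
#'   on the mesh surface.
#' @param tol convergence tolerance in mm.
#' @param max_iter maximum iterations.
#' @param init optional initial Cz guess; defaults to the topmost mesh
#'   vertex.
#' @return Cz as a length-3 point with attribute `iterations`.
#' @export
place_cz <- function(mesh, fiducials, tol = 0.1, max_iter = 50L,
                     init = NULL) {
  fid <- check_fiducials(fiducials)
  cz <- if (is.null(init)) mesh$vertices[which.max(mesh$vertices[, 3L]), ]
        else as.numeric(init)
  for (it in seq_len(max_iter)) {
    arc1 <- plane_section_arc(mesh, fid["Nz", ], fid["Iz", ], cz)
    cz1 <- point_at_fraction(arc1, 0.5)
    arc2 <- plane_section_arc(mesh, fid["AL", ], fid["AR", ], cz1)
    cz2 <- point_at_fraction(arc2, 0.5)
    moved <- vnorm(cz2 - cz)
    cz <- cz2
    if (moved < tol) {
      attr(cz, "iterations") <- it
      return(cz)
    }
  }
  stop(sprintf("Cz iteration did not converge in %d iterations", max_iter))
}

check_fiducials <- function(fiducials) {
  fid <- as.matrix(fiducials)
  need <- c("Nz", "Iz", "AL", "AR")
  if (is.null(rownames(fid)) || !all(need %in% rownames(fid)))
    stop("fiducials must be a matrix with rows Nz, Iz, AL, AR")
  fid[need, , drop = FALSE]
}

# montage definition table: how each label is constructed. Curves:
#   midline  Nz -> Iz over Cz, fractions of the full arc
#   coronal  AL -> AR over Cz
#   ring     circumferential curve Fpz -> T3 -> Oz -> T4 -> Fpz,
#            fractions of the full ring measured from Fpz via the left side
#   rows     transverse curves left-ring -> midline -> right-ring,
#            fractions of the full left-to-right curve
montage_definitions <- function(system = c("10-20", "10-10")) {
  system <- match.arg(system)
  mid <- data.frame(curve = "midline",
                    label = c("Fpz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz",
                              "POz", "Oz"),
                    fraction = seq(0.1, 0.9, 0.1))
  cor <- data.frame(curve = "coronal",
                    label = c("T3", "C5", "C3", "C1", "Cz2", "C2", "C4",
                              "C6", "T4"),
                    fraction = seq(0.1, 0.9, 0.1))
  ring <- data.frame(curve = "ring",
                     label = c("Fp1", "AF7", "F7", "FT7", "T3r", "TP7", "T5",
                               "PO7", "O1", "Ozr", "O2", "PO8", "T6", "TP8",
                               "T4r", "FT8", "F8", "AF8", "Fp2"),
                     fraction = seq(0.05, 0.95, 0.05))
  rows <- rbind(
    data.frame(curve = "row.F", left = "F7", mid = "Fz", right = "F8",
               label = c("F5", "F3", "F1", "Fzr", "F2", "F4", "F6"),
               fraction = seq(1, 7) / 8),
    data.frame(curve = "row.FC", left = "FT7", mid = "FCz", right = "FT8",
               label = c("FC5", "FC3", "FC1", "FCzr", "FC2", "FC4", "FC6"),
               fraction = seq(1, 7) / 8),
    data.frame(curve = "row.CP", left = "TP7", mid = "CPz", right = "TP8",
               label = c("CP5", "CP3", "CP1", "CPzr", "CP2", "CP4", "CP6"),
               fraction = seq(1, 7) / 8),
    data.frame(curve = "row.P", left = "T5", mid = "Pz", right = "T6",
               label = c("P5", "P3", "P1", "Pzr", "P2", "P4", "P6"),
               fraction = seq(1, 7) / 8),
    data.frame(curve = "row.AF", left = "AF7", mid = "AFz", right = "AF8",
               label = c("AF3", "AFzr", "AF4"), fraction = c(1, 2, 3) / 4),
    data.frame(curve = "row.PO", left = "PO7", mid = "POz", right = "PO8",
               label = c("PO3", "POzr", "PO4"), fraction = c(1, 2, 3) / 4))
  if (system == "10-20") {
    mid <- mid[mid$label %in% c("Fpz", "Fz", "Cz", "Pz", "Oz"), ]
    cor <- cor[cor$label %in% c("T3", "C3", "Cz2", "C4", "T4"), ]
    ring <- ring[ring$label %in% c("Fp1", "F7", "T3r", "T5", "O1", "Ozr",
                                   "O2", "T6", "T4r", "F8", "Fp2"), ]
    rows <- rbind(
      data.frame(curve = "row.F", left = "F7", mid = "Fz", right = "F8",
                 label = c("F3", "Fzr", "F4"), fraction = c(1, 2, 3) / 4),
      data.frame(curve = "row.P", left = "T5", mid = "Pz", right = "T6",
                 label = c("P3", "Pzr", "P4"), fraction = c(1, 2, 3) / 4))
  }
  list(midline = mid, coronal = cor, ring = ring, rows = rows)
}

#' Virtual 10-20 / 10-10 montage on a scalp mesh
#'
#' Implements the deterministic arc-subdivision construction of scalp
#' positions from the four fiducials: the midline curve Nz-Cz-Iz and the
#' central coronal curve AL-Cz-AR are subdivided at 10% steps; the
#' circumferential ring through Fpz, T3, Oz and T4 at 5%-of-ring steps; the
#' remaining positions come from transverse curves joining a left ring
#' point, a midline point and a right ring point, subdivided into 4 (10-20)
#' or 8 (10-10) equal arcs. Every position carries its curve and fraction
#' as provenance. The 10-20 montage comprises exactly 25 positions: the 19
#' classic electrode sites plus Fpz, Oz and the four fiducials.
#'
#' @inheritParams place_cz
#' @param system `"10-20"` or `"10-10"`.
#' @return an object of class `tenten_montage`: a data.frame with columns
#'   `label`, `x_mm`, `y_mm`, `z_mm`, `curve`, `fraction`, plus attributes
#'   `system` and `fiducials`.
#' @export
place_montage <- function(mesh, fiducials, system = c("10-20", "10-10"),
                          tol = 0.1, max_iter = 50L) {
  system <- match.arg(system)
  fid <- check_fiducials(fiducials)
  defs <- montage_definitions(system)
  cz <- place_cz(mesh, fid, tol = tol, max_iter = max_iter)

  pos <- list()
  add <- function(label, p, curve, fraction) {
    pos[[length(pos) + 1L]] <<- data.frame(
      label = label, x_mm = p[1L], y_mm = p[2L], z_mm = p[3L],
      curve = curve, fraction = fraction, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(fid))) add(rownames(fid)[i], fid[i, ], "fiducial", NA)

  # midline and central coronal curves
  arc_mid <- plane_section_arc(mesh, fid["Nz", ], fid["Iz", ], cz)
  for (i in seq_len(nrow(defs$midline)))
    add(defs$midline$label[i],
        point_at_fraction(arc_mid, defs$midline$fraction[i]),
        "midline", defs$midline$fraction[i])
  arc_cor <- plane_section_arc(mesh, fid["AL", ], fid["AR", ], cz)
  for (i in seq_len(nrow(defs$coronal)))
    add(defs$coronal$label[i],
        point_at_fraction(arc_cor, defs$coronal$fraction[i]),
        "coronal", defs$coronal$fraction[i])

  tab <- do.call(rbind, pos)
  get_pos <- function(lab) unlist(tab[match(lab, tab$label), c("x_mm", "y_mm", "z_mm")])

  # circumferential ring through Fpz, T3, Oz, T4
  anchors <- rbind(Fpz = get_pos("Fpz"), T3 = get_pos("T3"),
                   Oz = get_pos("Oz"), T4 = get_pos("T4"))
  ringf <- ring_curve(mesh, anchors)
  for (i in seq_len(nrow(defs$ring)))
    add(defs$ring$label[i], ringf(defs$ring$fraction[i]),
        "ring", defs$ring$fraction[i])
  tab <- do.call(rbind, pos)

  # transverse rows (third anchor = the corresponding midline point)
  rows <- defs$rows
  for (curve in unique(rows$curve)) {
    rr <- rows[rows$curve == curve, ]
    left <- get_pos(canonical_label(rr$left[1L]))
    right <- get_pos(canonical_label(rr$right[1L]))
    midp <- get_pos(canonical_label(rr$mid[1L]))
    arc <- plane_section_arc(mesh, left, right, midp)
    for (i in seq_len(nrow(rr)))
      add(rr$label[i], point_at_fraction(arc, rr$fraction[i]),
          curve, rr$fraction[i])
    tab <- do.call(rbind, pos)
  }

  out <- do.call(rbind, pos)
  # duplicate construction labels (Cz2, T3r, Fzr, ...) are redundancy checks
  # of the construction; keep the canonical instance only
  out <- out[!grepl("r$|2$", out$label) | out$label %in%
               c("Fp2", "C2", "F2", "FC2", "CP2", "P2", "O2", "AF2", "PO2"), ]
  rownames(out) <- NULL
  structure(out, class = c("tenten_montage", "data.frame"),
            system = system, fiducials = fid)
}

canonical_label <- function(lab) sub("r$", "", lab)

# parametrization of the closed circumferential curve: best-fit plane of
# the four anchors, closed mesh section, anchors snapped onto the loop,
# each quarter subdivided by arc length so anchors sit exactly at
# fractions 0, .25, .5, .75
ring_curve <- function(mesh, anchors) {
  ctr <- colMeans(anchors)
  sv <- svd(sweep(anchors, 2L, ctr))
  normal <- sv$v[, 3L]
  loops <- section_polylines(mesh, normal, sum(normal * ctr))
  loops <- Filter(function(L) L$closed, loops)
  if (length(loops) == 0L) stop("ring plane produced no closed section")
  score <- vapply(loops, function(L)
    sum(vapply(seq_len(4L), function(i)
      min_dist_to_polyline(L$pts, anchors[i, ], closed = TRUE)$dist, 0)), 0)
  P <- loops[[which.min(score)]]$pts
  Pc <- rbind(P, P[1L, ])
  seglen <- sqrt(rowSums(diff(Pc)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s_anchor <- vapply(seq_len(4L), function(i)
    min_dist_to_polyline(P, anchors[i, ], closed = TRUE)$s, 0)
  # orient so the order Fpz -> T3 -> Oz -> T4 is increasing
  rel <- (s_anchor - s_anchor[1L]) %% total
  if (rel[2L] > rel[4L]) {  # left side should come first
    P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
    Pc <- rbind(P, P[1L, ])
    seglen <- sqrt(rowSums(diff(Pc)^2))
    cum <- c(0, cumsum(seglen))
    s_anchor <- vapply(seq_len(4L), function(i)
      min_dist_to_polyline(P, anchors[i, ], closed = TRUE)$s, 0)
    rel <- (s_anchor - s_anchor[1L]) %% total
  }
  if (!(rel[2L] < rel[3L] && rel[3L] < rel[4L]))
    stop("ring anchors out of cyclic order; mesh or fiducials degenerate")
  bounds <- c(0, rel[2L], rel[3L], rel[4L], total)
  function(f) {
    f <- f %% 1
    q <- findInterval(f, c(0, 0.25, 0.5, 0.75), rightmost.closed = FALSE)
    q <- max(1L, min(q, 4L))
    local <- (f - c(0, 0.25, 0.5, 0.75)[q]) / 0.25
    s <- bounds[q] + local * (bounds[q + 1L] - bounds[q])
    point_at_s(Pc, cum, (s + s_anchor[1L]) %% total)
  }
}

#' @export
print.tenten_montage <- function(x, ...) {
  cat(sprintf("tenten_montage (%s): %d positions\n",
              attr(x, "system"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 8L), digits = 4)
  if (nrow(x) > 8L) cat("...\n")
  invisible(x)
}

#' Montage coordinates as a label-keyed matrix
#' @param montage a `tenten_montage`.
#' @return n x 3 matrix with label rownames.
#' @export
montage_matrix <- function(montage) {
  m <- as.matrix(as.data.frame(montage)[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- montage$label
  m
}

#' Nearest-neighbor distances within a montage
#'
#' For each montage position, the Euclidean distance to the closest other
#' position — the "pitch" of the system against which cortical landmark
#' dispersion is compared.
#'
#' @param montage a `tenten_montage` (or any matrix of positions).
#' @return named numeric vector of distances (mm).
#' @export
nearest_neighbor_distances <- function(montage) {
  m <- if (inherits(montage, "tenten_montage")) montage_matrix(montage)
       else as.matrix(montage)
  if (nrow(m) < 2L) stop("need at least two positions")
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  stats::setNames(apply(d, 1L, min), rownames(m))
}
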