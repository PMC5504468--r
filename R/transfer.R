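#' Choose the three neighboring montage positions for a cortical point
#'
#' The three montage positions nearest the cortical point (Euclidean),
#' subject to the three vectors from the pre-auricular midpoint M being
#' linearly independent (condition number below `cond_max`). If the
#' nearest triple is degenerate, its farthest member is replaced by the
#' next-nearest candidate. Ties are broken deterministically by label
#' order.
#'
#' @param cp cortical point (length-3, mm).
#' @param montage a `tenten_montage`.
#' @param M pre-auricular midpoint (AL + AR) / 2.
#' @param cond_max maximum accepted condition number of the vector triple.
#' @param rank_point optional point used for the distance ranking instead
#'   of `cp` itself (e.g. the scalp projection of a deep landmark).
#' @return character vector of three montage labels.
#' @export
choose_neighbors <- function(cp, montage, M, cond_max = 1e6,
                             rank_point = cp) {
  m <- montage_matrix(montage)
  if (nrow(m) < 3L) stop("montage must have at least 3 positions")
  d <- sqrt(rowSums(sweep(m, 2L, as.numeric(rank_point))^2))
  ord <- order(d, rownames(m))
  cand <- rownames(m)[ord]
  # greedy nearest-first: accept a candidate only while the growing vector
  # set stays well conditioned, so a degenerate (e.g. collinear) nearer
  # candidate is passed over for the next-nearest independent one
  triple <- character(0)
  for (lab in cand) {
    V <- t(m[c(triple, lab), , drop = FALSE]) - as.numeric(M)
    sv <- svd(V, nu = 0L, nv = 0L)$d
    cond <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
    if (cond < cond_max) triple <- c(triple, lab)
    if (length(triple) == 3L) return(triple)
  }
  stop("no linearly independent montage triple found")
}

#' Three-vector decomposition of a cortical point
#'
#' Expresses a cortical point CP as
#' `CP = M + a1 (L1 - M) + a2 (L2 - M) + a3 (L3 - M)` where M is the
#' pre-auricular midpoint and L1-L3 are three neighboring scalp positions:
#' the unique solution of the 3 x 3 linear system.
#'
#' @param cp cortical point (length-3, mm).
#' @param M pre-auricular midpoint.
#' @param L1,L2,L3 the three reference positions.
#' @param labels optional character labels of L1-L3, stored for transfer.
#' @return object of class `vector_coefficients`: `a` (length-3), `labels`,
#'   `M`, `residual` (mm).
#' @export
decompose <- function(cp, M, L1, L2, L3, labels = c("L1", "L2", "L3")) {
  A <- cbind(as.numeric(L1) - as.numeric(M),
             as.numeric(L2) - as.numeric(M),
             as.numeric(L3) - as.numeric(M))
  rhs <- as.numeric(cp) - as.numeric(M)
  a <- tryCatch(solve(A, rhs),
                error = function(e) stop("singular reference system"))
  res <- vnorm(A %*% a - rhs)
  structure(list(a = as.numeric(a), labels = labels, M = as.numeric(M),
                 residual = res),
            class = "vector_coefficients")
}

#' @export
print.vector_coefficients <- function(x, ...) {
  cat(sprintf("vector_coefficients (%s): a = (%.4f, %.4f, %.4f)\n",
              paste(x$labels, collapse = ", "), x$a[1L], x$a[2L], x$a[3L]))
  invisible(x)
}

#' Recompose a cortical point in a template space
#'
#' Applies source-space coefficients to the corresponding template
#' vectors: `CPt = Mt + a1 (L1t - Mt) + a2 (L2t - Mt) + a3 (L3t - Mt)`.
#'
#' @param coeffs a `vector_coefficients` from [decompose()].
#' @param Mt template pre-auricular midpoint.
#' @param L1t,L2t,L3t template positions for the same three labels.
#' @return length-3 template-space point (mm).
#' @export
recompose <- function(coeffs, Mt, L1t, L2t, L3t) {
  Mt <- as.numeric(Mt)
  as.numeric(Mt +
    coeffs$a[1L] * (as.numeric(L1t) - Mt) +
    coeffs$a[2L] * (as.numeric(L2t) - Mt) +
    coeffs$a[3L] * (as.numeric(L3t) - Mt))
}

#' Back-project a template-space cortical point onto the scalp
#'
#' Scales the three coefficients by one common factor — i.e. extends the
#' ray from the pre-auricular midpoint through the point — to its
#' outermost scalp intersection.
#'
#' @param cp_t template-space cortical point.
#' @param Mt template pre-auricular midpoint.
#' @param scalp template scalp [triangle_mesh()].
#' @return length-3 scalp point with attribute `scale` (the common
#'   coefficient factor s).
#' @export
backproject_to_scalp <- function(cp_t, Mt, scalp) {
  v <- as.numeric(cp_t) - as.numeric(Mt)
  if (vnorm(v) < 1e-9) stop("cortical point coincides with the midpoint")
  hit <- ray_surface_intersection(scalp, as.numeric(Mt), v)
  out <- hit$point
  attr(out, "scale") <- hit$t / vnorm(v)
  out
}

#' Transfer a cohort's cortical landmarks to a template scalp
#'
#' For every subject and landmark: pick the three neighboring montage
#' positions in the subject's own space (ranked by the landmark's scalp
#' projection, so deep landmarks select lateral rather than vertex
#' neighbors), decompose against the subject's pre-auricular midpoint,
#' recompose with the template's montage, and back-project onto the
#' template scalp. Subjects without a valid montage are excluded with a
#' logged reason.
#'
#' @param cohort a `synthetic_cohort`, or a list of subjects each carrying
#'   `id`, `landmarks`, `fiducials`, `scalp`.
#' @param montages named list of `tenten_montage` objects by subject id
#'   (must include the template).
#' @param template_id subject id of the template head.
#' @param template the template subject (taken from the cohort by id if
#'   omitted).
#' @param labels landmark labels to transfer (default all, 1-20).
#' @param exclude subject ids to exclude (logged).
#' @return object of class `transfer_result`: data.frame with one row per
#'   subject x landmark x hemisphere (coefficients, template point, scalp
#'   point, scale factor), with the template id and exclusions as
#'   attributes.
#' @export
transfer_cohort <- function(cohort, montages, template_id,
                            template = NULL, labels = 1:20,
                            exclude = character()) {
  subjects <- if (inherits(cohort, "synthetic_cohort")) cohort$subjects
              else cohort
  ids <- vapply(subjects, `[[`, "", "id")
  if (is.null(template)) {
    if (!template_id %in% ids) stop("template not in cohort")
    template <- subjects[[match(template_id, ids)]]
  }
  if (!template_id %in% names(montages))
    stop("no montage for the template")
  tm <- montage_matrix(montages[[template_id]])
  Mt <- (template$fiducials["AL", ] + template$fiducials["AR", ]) / 2

  dropped <- exclude[exclude %in% ids]
  for (id in setdiff(ids, exclude)) {
    if (!id %in% names(montages)) {
      message("excluding ", id, ": no montage available")
      dropped <- c(dropped, id)
    }
  }
  keep <- setdiff(ids, dropped)

  rows <- list()
  for (id in keep) {
    s <- subjects[[match(id, ids)]]
    mo <- montages[[id]]
    mm <- montage_matrix(mo)
    Ms <- (s$fiducials["AL", ] + s$fiducials["AR", ]) / 2
    lm <- s$landmarks[s$landmarks$label %in% labels, , drop = FALSE]
    for (i in seq_len(nrow(lm))) {
      cp <- c(lm$x_mm[i], lm$y_mm[i], lm$z_mm[i])
      rank_pt <- tryCatch(
        as.numeric(backproject_to_scalp(cp, Ms, s$scalp)),
        error = function(e) cp)
      trip <- choose_neighbors(cp, mo, Ms, rank_point = rank_pt)
      co <- decompose(cp, Ms, mm[trip[1L], ], mm[trip[2L], ],
                      mm[trip[3L], ], labels = trip)
      cpt <- recompose(co, Mt, tm[trip[1L], ], tm[trip[2L], ],
                       tm[trip[3L], ])
      sp <- backproject_to_scalp(cpt, Mt, template$scalp)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, label = lm$label[i],
        hemisphere = lm$hemisphere[i],
        a1 = co$a[1L], a2 = co$a[2L], a3 = co$a[3L],
        L1 = trip[1L], L2 = trip[2L], L3 = trip[3L],
        xt_mm = cpt[1L], yt_mm = cpt[2L], zt_mm = cpt[3L],
        xs_mm = sp[1L], ys_mm = sp[2L], zs_mm = sp[3L],
        scale = attr(sp, "scale"), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("transfer_result", "data.frame"),
            template_id = template_id, excluded = dropped)
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("transfer_result: %d transferred points from %d subjects onto template %s\n",
              nrow(x), length(unique(x$subject_id)), attr(x, "template_id")))
  if (length(attr(x, "excluded")) > 0L)
    cat("  excluded:", paste(attr(x, "excluded"), collapse = ", "), "\n")
  invisible(x)
}

#' Cross-subject dispersion of transferred landmarks
#'
#' Per landmark (and hemisphere): the centroid of the transferred scalp
#' points, the distances of each subject's point from that centroid, and
#' box-and-whisker summaries — median, quartiles (linear-interpolation
#' convention) and Tukey whiskers (the largest value below the upper
#' quartile + 1.5 IQR, and the smallest above the lower quartile -
#' 1.5 IQR).
#'
#' @param transfer a `transfer_result` (or a data.frame with `label`,
#'   `hemisphere`, `xs_mm`, `ys_mm`, `zs_mm`).
#' @return object of class `dispersion_stats`: one row per landmark x
#'   hemisphere with `n`, `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`
#'   (mm), plus a `distances` attribute (named list).
#' @export
dispersion <- function(transfer) {
  df <- as.data.frame(transfer)
  groups <- split(df, list(df$label, df$hemisphere), drop = TRUE)
  rows <- list()
  dists <- list()
  for (g in groups) {
    if (nrow(g) < 2L) next
    P <- as.matrix(g[, c("xs_mm", "ys_mm", "zs_mm")])
    ctr <- colMeans(P)
    d <- sqrt(rowSums(sweep(P, 2L, ctr)^2))
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3L] - q[1L]
    lo <- min(d[d >= q[1L] - 1.5 * iqr])
    hi <- max(d[d <= q[3L] + 1.5 * iqr])
    key <- sprintf("%d_%s", g$label[1L], g$hemisphere[1L])
    dists[[key]] <- unname(d)
    rows[[length(rows) + 1L]] <- data.frame(
      label = g$label[1L], hemisphere = g$hemisphere[1L], n = nrow(g),
      cx_mm = ctr[1L], cy_mm = ctr[2L], cz_mm = ctr[3L],
      median = q[2L], q1 = q[1L], q3 = q[3L],
      whisker_lo = lo, whisker_hi = hi, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("dispersion_stats", "data.frame"),
            distances = dists)
}

#' @export
print.dispersion_stats <- function(x, ...) {
  cat(sprintf("dispersion_stats: %d landmark groups\n", nrow(x)))
  cat(sprintf("  median of per-landmark medians: %.1f mm (max %.1f mm)\n",
              stats::median(x$median), max(x$median)))
  invisible(x)
}

#' Box-and-whisker plot of per-landmark dispersion
#'
#' One box per landmark x hemisphere of the distances from the per-landmark
#' centroid on the template scalp; optionally a final box with the
#' montage's nearest-neighbor distances for comparison.
#'
#' @param x a `dispersion_stats`.
#' @param nn_distances optional numeric vector of montage nearest-neighbor
#'   distances to append as a reference box.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.dispersion_stats <- function(x, nn_distances = NULL, ...) {
  dists <- attr(x, "distances")
  if (!is.null(nn_distances)) dists <- c(dists, list(`10-10 NN` = nn_distances))
  graphics::boxplot(dists, las = 2, ylab = "distance from centroid (mm)",
                    main = "Transferred-landmark dispersion", ...)
  invisible(x)
}
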