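#' Adjust a landmark to the lateral cortical surface
#'
#' Junction landmarks identified on slice images tend to lie beneath the
#' lateral cortical surface; to avoid depth variability, they are moved
#' laterally (along +x for the right hemisphere, -x for the left) to the
#' outermost brain-surface crossing, leaving y and z unchanged. If the
#' lateral ray misses the surface, the nearest surface point is used
#' instead (reported via a message).
#'
#' @param point length-3 landmark position (mm).
#' @param brain brain-surface [triangle_mesh()].
#' @param hemisphere `"L"` or `"R"`.
#' @return adjusted length-3 point on the surface.
#' @export
adjust_to_surface <- function(point, brain, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  dir <- c(if (hemisphere == "L") -1 else 1, 0, 0)
  # cast from the midsagittal line at the landmark's (y, z) so that points
  # lying slightly outside the surface still adjust inward
  origin <- c(0, as.numeric(point)[2:3])
  out <- tryCatch(ray_surface_intersection(brain, origin, dir)$point,
                  error = function(e) NULL)
  if (is.null(out)) {
    message("lateral ray missed the surface; using nearest surface point")
    out <- closest_point_on_mesh(brain, as.numeric(point))$point
  }
  out
}

#' Distance-ratio specifications for the topological-relationship table
#'
#' One row per analyzed landmark: the ratio d(a,b)/d(b,c) of Euclidean
#' distances between landmark b and the two reference extremes, either
#' direct 3-D distances or distances after projection to the sagittal or
#' coronal plane. Anterior-posterior rows run frontal pole (2) to
#' occipital pole (5); height rows run vertex (1) to brain base (4). A
#' declining ratio means an anterior (or dorsal) shift of landmark b. Rows
#' are keyed by their definition string; the table is data and can be
#' edited without code changes.
#'
#' @return data.frame with columns `landmark`, `definition`, `a`, `b`, `c`,
#'   `mode` (`direct`, `sagittal`, `coronal`) and `declining_means`.
#' @export
ratio_specs <- function() {
  data.frame(
    landmark  = c(7L, 8L, 9L, 10L, 16L, 12L, 15L, 20L, 13L, 14L, 20L, 17L, 18L),
    definition = c("(2-7)/(7-5)", "(2-8)/(8-5)", "(2-9)/(9-5)", "(2-10)/(10-5)",
                   "(2-16)/(16-5)", "(2-12)/(12-5)", "(2-15)/(15-5)",
                   "(2-20)/(20-5)", "(2-13)/(13-5)", "(1-14)/(14-4)",
                   "(1-20)/(20-4)", "(1-17)/(17-4)", "(1-18)/(18-4)"),
    a = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L),
    b = c(7L, 8L, 9L, 10L, 16L, 12L, 15L, 20L, 13L, 14L, 20L, 17L, 18L),
    c = c(5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 4L, 4L, 4L, 4L),
    mode = c("sagittal", "direct", "direct", "direct", "direct", "direct",
             "sagittal", "direct", "direct", "coronal", "coronal", "coronal",
             "coronal"),
    declining_means = c(rep("anterior shift", 9L), "dorsal shift",
                        "dorsal shift", "dorsal shift", "dorsal shift"),
    stringsAsFactors = FALSE)
}

# landmarks whose slice-defined positions sit beneath the lateral surface
# and get surface-adjusted before ratio computation
junction_labels <- function() c(8L, 9L, 10L, 11L, 12L, 20L)

#' Distance ratio for one subject
#'
#' Computes d(a,b)/d(b,c) for a ratio specification, after applying the
#' spec's projection mode to all three landmark positions.
#'
#' @param landmarks one subject's landmark data.frame.
#' @param spec one row of [ratio_specs()] (or a list with `a`, `b`, `c`,
#'   `mode`).
#' @param hemisphere `"L"` or `"R"`.
#' @return dimensionless ratio.
#' @export
ratio <- function(landmarks, spec, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  labels <- c(spec$a, spec$b, spec$c)
  pts <- landmark_matrix(landmarks, labels, hemisphere)
  if (spec$mode != "direct")
    pts <- project(pts, if (spec$mode == "sagittal") "sagittal" else "coronal")
  dab <- vnorm(pts[1L, ] - pts[2L, ])
  dbc <- vnorm(pts[2L, ] - pts[3L, ])
  if (dbc < 1e-12) stop("undefined ratio: d(b, c) is zero")
  dab / dbc
}

#' Pearson correlation with exact two-tailed p
#'
#' Pearson's r with the two-tailed p-value from the t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom —
#' the test behind both the ratio-age table and the PC-score age
#' regressions.
#'
#' @param xs,ys paired numeric samples (n >= 3), or `r` given directly.
#' @param r,n alternatively, a correlation and sample size.
#' @return object of class `correlation_result`: `r`, `n`, `t`, `p`.
#' @examples
#' pearson_with_p(r = -0.620, n = 16)  # p rounds to 0.010
#' @export
pearson_with_p <- function(xs = NULL, ys = NULL, r = NULL, n = NULL) {
  if (is.null(r)) {
    if (length(xs) != length(ys)) stop("xs and ys must be the same length")
    n <- length(xs)
    if (n < 3L) stop("need at least 3 pairs")
    if (stats::sd(xs) < 1e-300 || stats::sd(ys) < 1e-300)
      stop("zero variance input")
    r <- stats::cor(xs, ys)
  }
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  }
  structure(list(r = r, n = as.integer(n), t = t, p = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), t = %.3f, two-tailed p = %.3f\n",
              x$r, x$n, x$t, round(x$p, 3)))
  invisible(x)
}

#' Topological-relationship table: ratio-age correlations across a cohort
#'
#' For every ratio specification and hemisphere, computes the distance
#' ratio per subject (after lateral surface adjustment of junction
#' landmarks when brain meshes are supplied) and correlates it with age.
#' P-values are printed to 3 decimals (round-half-even); raw values are
#' retained.
#'
#' @param landmarks stacked landmark data.frame for the cohort.
#' @param ages named numeric vector of ages by subject id (taken from the
#'   table if omitted).
#' @param specs ratio specification table, default [ratio_specs()].
#' @param brains optional named list of brain meshes by subject id; when
#'   given, junction landmarks are surface-adjusted first.
#' @return data.frame of class `topo_table`: `definition`, `landmark`,
#'   `hemisphere`, `mode`, `n`, `r`, `t`, `p`, `p_printed`,
#'   `declining_means`.
#' @export
table1_analysis <- function(landmarks, ages = NULL, specs = ratio_specs(),
                            brains = NULL) {
  subjects <- unique(landmarks$subject_id)
  if (length(subjects) < 3L) stop("need at least 3 subjects")
  if (is.null(ages)) {
    ages <- vapply(subjects, function(s)
      landmarks$age_months[landmarks$subject_id == s][1L], 0)
    names(ages) <- subjects
  }
  if (!is.null(brains))
    landmarks <- adjust_junctions(landmarks, brains)

  rows <- list()
  for (i in seq_len(nrow(specs))) {
    for (hemi in c("L", "R")) {
      vals <- vapply(subjects, function(s) {
        sub <- landmarks[landmarks$subject_id == s, , drop = FALSE]
        tryCatch(ratio(sub, specs[i, ], hemi), error = function(e) NA_real_)
      }, 0)
      ok <- is.finite(vals)
      if (sum(ok) < 3L) {
        warning("skipping ", specs$definition[i], " ", hemi,
                ": missing landmarks")
        next
      }
      cr <- pearson_with_p(ages[subjects][ok], vals[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        definition = specs$definition[i], landmark = specs$landmark[i],
        hemisphere = hemi, mode = specs$mode[i], n = cr$n, r = cr$r,
        t = cr$t, p = cr$p, p_printed = round(cr$p, 3L),
        declining_means = specs$declining_means[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("topo_table", "data.frame"))
}

#' @export
print.topo_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$r <- sprintf("%.3f", df$r)
  df$p <- sprintf("%.3f", df$p_printed)
  print.data.frame(df[, c("definition", "hemisphere", "mode", "n", "r", "p",
                          "declining_means")], row.names = FALSE)
  invisible(x)
}

# surface-adjust the junction landmarks of every subject with a mesh
adjust_junctions <- function(landmarks, brains) {
  idx <- which(landmarks$label %in% junction_labels() &
                 landmarks$subject_id %in% names(brains))
  for (i in idx) {
    mesh <- brains[[landmarks$subject_id[i]]]
    p <- adjust_to_surface(
      c(landmarks$x_mm[i], landmarks$y_mm[i], landmarks$z_mm[i]),
      mesh, landmarks$hemisphere[i])
    landmarks$x_mm[i] <- p[1L]
    landmarks$y_mm[i] <- p[2L]
    landmarks$z_mm[i] <- p[3L]
  }
  landmarks
}
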