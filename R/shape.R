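#' Landmark configurations for shape analysis
#'
#' Assembles one k x 3 configuration per subject from a stacked landmark
#' table, with a shared ordered label list. The cortical configuration
#' uses the 10 macroanatomical landmarks 7-15 and 20 of each hemisphere
#' (k = 20); extremal landmarks (1-6) and the dependent landmarks (16-19)
#' are excluded because they are not defined by distinct cortical
#' structures (or depend on landmark 11).
#'
#' @param landmarks stacked landmark data.frame (see [read_landmarks()]).
#' @param set `"cortex"` for the 10-per-hemisphere cortical set, or a
#'   custom integer vector of labels taken from both hemispheres.
#' @param ages optional named vector of ages (by subject id); taken from
#'   the table's `age_months` otherwise.
#' @return list of class `configuration_set`: `coords` (k x 3 x n array),
#'   `labels` (character, "<label>_<hemisphere>"), `subjects`, `ages`.
#' @export
configurations <- function(landmarks, set = "cortex", ages = NULL) {
  labels <- if (identical(set, "cortex")) c(7:15, 20L) else as.integer(set)
  subjects <- unique(landmarks$subject_id)
  keys <- as.vector(outer(labels, c("L", "R"), paste, sep = "_"))
  coords <- array(NA_real_, c(length(keys), 3L, length(subjects)),
                  dimnames = list(keys, c("x", "y", "z"), subjects))
  age_out <- numeric(length(subjects))
  for (i in seq_along(subjects)) {
    sub <- landmarks[landmarks$subject_id == subjects[i], , drop = FALSE]
    coords[, , i] <- rbind(landmark_matrix(sub, labels, "L"),
                           landmark_matrix(sub, labels, "R"))
    age_out[i] <- sub$age_months[1L]
  }
  if (!is.null(ages)) age_out <- unname(ages[subjects])
  structure(list(coords = coords, labels = keys, subjects = subjects,
                 ages = age_out),
            class = "configuration_set")
}

#' Configuration set from per-subject montages
#'
#' The head configuration of the shape analysis: the 25-point virtual
#' 10-20 montage of each subject.
#'
#' @param montages named list of `tenten_montage` objects (one per subject).
#' @param ages named numeric vector of ages by subject id.
#' @return a `configuration_set`.
#' @export
montage_configurations <- function(montages, ages) {
  subjects <- names(montages)
  labels <- sort(montages[[1L]]$label)
  coords <- array(NA_real_, c(length(labels), 3L, length(subjects)),
                  dimnames = list(labels, c("x", "y", "z"), subjects))
  for (i in seq_along(subjects)) {
    m <- montage_matrix(montages[[i]])
    if (!all(labels %in% rownames(m)))
      stop("montage for ", subjects[i], " lacks labels: ",
           paste(setdiff(labels, rownames(m)), collapse = ", "))
    coords[, , i] <- m[labels, ]
  }
  structure(list(coords = coords, labels = labels, subjects = subjects,
                 ages = unname(ages[subjects])),
            class = "configuration_set")
}

#' Centroid size of a landmark configuration
#'
#' The scale measure of Procrustes analysis: the square root of the summed
#' squared distances of the landmarks from their centroid.
#'
#' @param config k x 3 coordinate matrix (mm).
#' @return centroid size in mm.
#' @export
centroid_size <- function(config) {
  x <- as.matrix(config)
  sqrt(sum(sweep(x, 2L, colMeans(x))^2))
}

# optimal proper rotation taking X onto Y (reflections forbidden)
procrustes_rotation <- function(X, Y) {
  M <- crossprod(X, Y)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Generalized Procrustes analysis
#'
#' Fits Procrustes shape coordinates to a set of landmark configurations:
#' each configuration is translated to the origin, scaled to unit centroid
#' size, and rotated by the optimal proper rotation to the running
#' consensus, which is re-estimated until it stabilizes (partial
#' Procrustes: no additional rotational rescaling beyond unit centroid
#' size). The converged solution is put in a canonical orientation — the
#' consensus' principal axes aligned with the coordinate axes, sign-fixed —
#' so the result does not depend on input ordering or on arbitrary rigid
#' motions or rescalings of any input.
#'
#' @param configs a `configuration_set` (see [configurations()]), or a
#'   k x 3 x n array.
#' @param tol consensus change (root summed squared difference) declaring
#'   convergence.
#' @param max_iter maximum consensus updates.
#' @return an object of class `gpa`: `consensus` (k x 3, unit centroid
#'   size), `aligned` (k x 3 x n Procrustes shape coordinates),
#'   `centroid_sizes` (mm), `labels`, `subjects`, `ages`, `iterations`,
#'   `rss` (total squared deviation from the consensus).
#' @seealso [pca_shapes()], [regress_scores_on_age()]
#' @export
gpa <- function(configs, tol = 1e-8, max_iter = 100L) {
  cs <- if (inherits(configs, "configuration_set")) configs
        else list(coords = configs, labels = dimnames(configs)[[1L]],
                  subjects = dimnames(configs)[[3L]], ages = NULL)
  A <- cs$coords
  n <- dim(A)[3L]
  if (is.null(n) || n < 2L) stop("need at least two configurations")
  k <- dim(A)[1L]
  if (k < 4L) stop("need at least 4 landmarks")

  sizes <- numeric(n)
  X <- A
  for (i in seq_len(n)) {
    xi <- A[, , i]
    xi <- sweep(xi, 2L, colMeans(xi))
    sizes[i] <- sqrt(sum(xi^2))
    if (sizes[i] < 1e-12) stop("degenerate configuration: zero centroid size")
    X[, , i] <- xi / sizes[i]
  }
  if (any(vapply(seq_len(n), function(i) qr(X[, , i])$rank, 0L) < 3L))
    stop("degenerate (rank < 3) configuration")

  consensus <- X[, , 1L]
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    for (i in seq_len(n))
      X[, , i] <- X[, , i] %*% procrustes_rotation(X[, , i], consensus)
    newc <- apply(X, c(1L, 2L), mean)
    newc <- sweep(newc, 2L, colMeans(newc))
    newc <- newc / sqrt(sum(newc^2))
    delta <- sqrt(sum((newc - consensus)^2))
    consensus <- newc
    if (delta < tol) break
    if (iterations >= max_iter)
      stop("generalized Procrustes analysis did not converge")
  }

  # canonical orientation: consensus principal axes onto coordinate axes
  R0 <- canonical_rotation(consensus)
  consensus <- consensus %*% R0
  for (i in seq_len(n)) X[, , i] <- X[, , i] %*% R0

  rss <- sum(vapply(seq_len(n), function(i) sum((X[, , i] - consensus)^2), 0))
  structure(list(consensus = consensus, aligned = X,
                 centroid_sizes = sizes, labels = cs$labels,
                 subjects = cs$subjects, ages = cs$ages,
                 iterations = iterations, rss = rss, tol = tol),
            class = "gpa")
}

# deterministic principal-axes rotation with an intrinsic sign convention:
# along each of the first two axes, the landmark with the largest
# magnitude projection projects positively; the third axis completes a
# right-handed frame. (Signs must come from the landmark projections, not
# the eigenvector components, to be invariant to the input frame.)
canonical_rotation <- function(C) {
  ev <- eigen(crossprod(sweep(C, 2L, colMeans(C))), symmetric = TRUE)
  V <- ev$vectors
  proj <- C %*% V
  for (j in 1:2) {
    i <- which.max(abs(proj[, j]))
    if (proj[i, j] < 0) V[, j] <- -V[, j]
  }
  V[, 3L] <- c(V[2L, 1L] * V[3L, 2L] - V[3L, 1L] * V[2L, 2L],
               V[3L, 1L] * V[1L, 2L] - V[1L, 1L] * V[3L, 2L],
               V[1L, 1L] * V[2L, 2L] - V[2L, 1L] * V[1L, 2L])
  V
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf("Generalized Procrustes fit: %d configurations, %d landmarks\n",
              dim(x$aligned)[3L], dim(x$aligned)[1L]))
  cat(sprintf("  converged in %d iterations; total squared deviation %.6g\n",
              x$iterations, x$rss))
  cat(sprintf("  centroid sizes %.1f-%.1f mm\n",
              min(x$centroid_sizes), max(x$centroid_sizes)))
  invisible(x)
}

#' @export
summary.gpa <- function(object, ...) {
  p <- pca_shapes(object)
  structure(list(fit = object, pca = p), class = "summary.gpa")
}

#' @export
print.summary.gpa <- function(x, ...) {
  print(x$fit)
  vf <- x$pca$variance_fractions
  cat("  variance fractions (first 4 PCs): ",
      paste(sprintf("%.1f%%", 100 * vf[seq_len(min(4L, length(vf)))]),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$fit$ages)) {
    r <- regress_scores_on_age(x$pca$scores[, 1L], x$fit$ages)
    cat(sprintf("  PC1 score vs age: r = %.3f, p = %.4f\n", r$r, r$p))
  }
  invisible(x)
}

#' @export
plot.gpa <- function(x, pc = NULL, ...) {
  C <- x$consensus
  plot(C[, 2L], C[, 3L], pch = 19, asp = 1,
       xlab = "y (Procrustes units)", ylab = "z (Procrustes units)",
       main = "Consensus configuration (lateral view)", ...)
  graphics::text(C[, 2L], C[, 3L], x$labels, pos = 3, cex = 0.6)
  for (i in seq_len(dim(x$aligned)[3L]))
    graphics::points(x$aligned[, 2L, i], x$aligned[, 3L, i],
                     pch = 1, cex = 0.4, col = "grey50")
  invisible(x)
}

#' Shape-space principal component analysis
#'
#' PCA of the mean-centered, flattened Procrustes shape coordinates. The
#' sign of each component is fixed deterministically (the largest-magnitude
#' loading element is positive), since PC sign is otherwise arbitrary.
#'
#' @param space a [gpa()] fit.
#' @return object of class `shape_pca`: `loadings` (3k x m), `scores`
#'   (n x m), `variance_fractions` (sums to 1), `center`.
#' @export
pca_shapes <- function(space) {
  stopifnot(inherits(space, "gpa"))
  n <- dim(space$aligned)[3L]
  if (n < 3L) stop("need at least 3 configurations for a PCA")
  Xf <- t(vapply(seq_len(n), function(i) as.vector(space$aligned[, , i]),
                 numeric(length(space$consensus))))
  ctr <- colMeans(Xf)
  Xc <- sweep(Xf, 2L, ctr)
  sv <- svd(Xc)
  m <- min(n - 1L, ncol(Xc))
  loadings <- sv$v[, seq_len(m), drop = FALSE]
  scores <- (Xc %*% loadings)
  ev <- sv$d[seq_len(m)]^2
  for (j in seq_len(m)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- space$subjects
  structure(list(loadings = loadings, scores = scores,
                 variance_fractions = ev / sum(ev), center = ctr,
                 labels = space$labels),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  vf <- x$variance_fractions
  cat("shape_pca:", length(vf), "components\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", vf[seq_len(min(6L, length(vf)))]), collapse = " "),
      if (length(vf) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Regression of PC scores on age
#'
#' Pearson correlation of per-subject principal component scores with age,
#' with the exact two-tailed p from the t transform on n - 2 degrees of
#' freedom (the same test used for the distance-ratio table).
#'
#' @param scores numeric vector of per-subject scores.
#' @param ages ages in months.
#' @return a `correlation_result` (see [pearson_with_p()]).
#' @export
regress_scores_on_age <- function(scores, ages) {
  pearson_with_p(ages, scores)
}
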