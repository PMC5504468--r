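random_configs <- function(n = 5L, k = 10L, seed = 1L) {
  set.seed(seed)
  base <- matrix(rnorm(k * 3L, sd = 30), k, 3L)
  A <- array(NA_real_, c(k, 3L, n),
             dimnames = list(paste0("p", seq_len(k)), c("x", "y", "z"),
                             paste0("s", seq_len(n))))
  for (i in seq_len(n)) A[, , i] <- base + matrix(rnorm(k * 3L, sd = 3), k, 3L)
  A
}

test_that("centroid size follows its definition", {
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(centroid_size(sq), sqrt(8))
  expect_equal(centroid_size(matrix(5, 4L, 3L)), 0)
  set.seed(3)
  X <- matrix(rnorm(30), 10L, 3L)
  expect_equal(centroid_size(3 * X), 3 * centroid_size(X))
})

test_that("GPA aligns similar configurations exactly", {
  A <- random_configs(n = 2L, seed = 11L)
  # B is a rotated, scaled, shifted copy of A
  R <- random_rotation()
  A[, , 2L] <- 2.5 * A[, , 1L] %*% t(R) + matrix(c(10, -4, 7), 10L, 3L,
                                                 byrow = TRUE)
  fit <- gpa(A)
  expect_lt(max(abs(fit$aligned[, , 1L] - fit$aligned[, , 2L])), 1e-9)
  expect_equal(fit$rss, 0, tolerance = 1e-15)
  # aligned configurations are centered at unit centroid size
  for (i in 1:2) {
    expect_lt(max(abs(colMeans(fit$aligned[, , i]))), 1e-9)
    expect_equal(sum(fit$aligned[, , i]^2), 1, tolerance = 1e-9)
  }
})

test_that("GPA is invariant to input order and similarity transforms", {
  A <- random_configs(n = 6L, seed = 21L)
  ref <- gpa(A)

  # arbitrary rigid motions and rescalings of each input
  set.seed(22)
  B <- A
  for (i in seq_len(dim(A)[3L])) {
    R <- random_rotation()
    B[, , i] <- runif(1, 0.5, 3) * A[, , i] %*% t(R) +
      matrix(rnorm(3, sd = 40), dim(A)[1L], 3L, byrow = TRUE)
  }
  fit_b <- gpa(B)
  expect_lt(max(abs(fit_b$aligned - ref$aligned)), 1e-6)

  # input order
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  fit_p <- gpa(A[, , perm])
  expect_lt(max(abs(fit_p$aligned - ref$aligned[, , perm])), 1e-6)

  # idempotence
  fit2 <- gpa(ref$aligned)
  expect_lt(max(abs(fit2$aligned - ref$aligned)), 1e-9)
})

test_that("GPA total deviation matches the closed-form SVD oracle", {
  A <- random_configs(n = 5L, seed = 31L)
  fit <- gpa(A)
  # at the fixed point, each configuration's squared deviation from the
  # consensus equals the closed-form orthogonal-Procrustes minimum
  # ||X||^2 + ||C||^2 - 2 (s1 + s2 + sign(det M) s3)
  C <- fit$consensus
  total <- 0
  for (i in seq_len(dim(A)[3L])) {
    X <- A[, , i]
    X <- sweep(X, 2L, colMeans(X))
    X <- X / sqrt(sum(X^2))
    M <- crossprod(X, C)
    s <- svd(M)$d
    total <- total + sum(X^2) + sum(C^2) -
      2 * (s[1L] + s[2L] + sign(det(M)) * s[3L])
  }
  expect_equal(fit$rss, total, tolerance = 1e-8)
})

test_that("reflections are not undone by GPA", {
  A <- random_configs(n = 4L, seed = 41L)
  fit <- gpa(A)
  B <- A
  B[, 1L, 2L] <- -B[, 1L, 2L]  # mirror one configuration
  fit_m <- gpa(B)
  d_orig <- sum((fit$aligned[, , 2L] - fit$consensus)^2)
  d_mirr <- sum((fit_m$aligned[, , 2L] - fit_m$consensus)^2)
  expect_gt(d_mirr, d_orig * 10)
})

test_that("shape PCA satisfies its algebraic contract", {
  A <- random_configs(n = 8L, seed = 51L)
  fit <- gpa(A)
  p <- pca_shapes(fit)
  vf <- p$variance_fractions
  expect_true(all(vf >= 0 & vf <= 1))
  expect_equal(sum(vf), 1, tolerance = 1e-9)

  # reconstruction: mean + scores %*% t(loadings) gives the data back
  n <- dim(fit$aligned)[3L]
  Xf <- t(vapply(seq_len(n), function(i) as.vector(fit$aligned[, , i]),
                 numeric(length(fit$consensus))))
  rec <- sweep(p$scores %*% t(p$loadings), 2L, p$center, "+")
  expect_lt(max(abs(rec - Xf)), 1e-9)

  # eigenvalue oracle: dense covariance eigendecomposition
  ev <- eigen(stats::cov(Xf), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(vf[seq_along(ev)], ev / sum(ev), tolerance = 1e-8)

  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(p$loadings))) {
    i <- which.max(abs(p$loadings[, j]))
    expect_gte(p$loadings[i, j], 0)
  }
})

test_that("variation on a single coordinate loads on one component", {
  A <- random_configs(n = 6L, seed = 61L)
  A[, , ] <- A[, , 1L]  # identical configurations ...
  A[1L, 1L, ] <- A[1L, 1L, ] + seq(0, 12, length.out = 6L)  # ... except one
  fit <- gpa(A)
  p <- pca_shapes(fit)
  expect_gt(p$variance_fractions[1L], 0.999)
})

test_that("PC score age regression recovers exact and null effects", {
  ages <- c(3, 6, 9, 13, 17, 22)
  r <- regress_scores_on_age(ages, ages)
  expect_equal(r$r, 1)
  expect_lt(r$p, 1e-12)
  expect_error(regress_scores_on_age(rep(1, 6), ages), "zero variance")

  # power on the generator's default effect size: PC1 of the cortical
  # configuration correlates with age in most replicates
  hits <- 0L
  nrep <- 25L
  for (i in seq_len(nrep)) {
    co <- make_cohort(growth_model(), n = 16L, seed = 3000L + i,
                      meshes = FALSE)
    fit <- gpa(configurations(cohort_landmarks(co), "cortex",
                              cohort_ages(co)))
    p <- pca_shapes(fit)
    res <- regress_scores_on_age(p$scores[, 1L], fit$ages)
    if (abs(res$r) > 0.4) hits <- hits + 1L
  }
  expect_gte(hits / nrep, 0.8)
})
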