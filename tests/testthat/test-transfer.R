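sphere_montage_fixture <- function() {
  m <- sphere_mesh(64L, 32L, radius = 80)
  mo <- place_montage(m, sphere_fiducials(80), "10-10")
  list(mesh = m, montage = mo, M = c(0, 0, 0))
}

test_that("neighbor choice is nearest-with-independence", {
  fx <- sphere_montage_fixture()
  mm <- montage_matrix(fx$montage)

  # a cortical point at a montage position selects it first
  trip <- choose_neighbors(mm["C3", ], fx$montage, fx$M)
  expect_identical(trip[1L], "C3")

  # random points match the exhaustive search under the constraint
  set.seed(31)
  for (i in 1:6) {
    cp <- craniocorr:::unitize(rnorm(3)) * 70
    trip <- choose_neighbors(cp, fx$montage, fx$M)
    d <- sqrt(rowSums(sweep(mm, 2L, cp)^2))
    ord <- order(d, rownames(mm))
    best <- NULL
    for (comb in utils::combn(ord[1:6], 3L, simplify = FALSE)) {
      V <- t(mm[comb, ]) - fx$M
      if (kappa(V, exact = TRUE) < 1e6) {
        if (is.null(best) || sum(d[comb]) < sum(d[best]) - 1e-12) best <- comb
      }
    }
    expect_setequal(trip, rownames(mm)[best])
  }

  # the three nearest positions span a degenerate (coplanar-with-M) set:
  # the third member is replaced by the fourth-nearest
  pts <- rbind(A = c(0, 10, 5), B = c(0, 20, 5), C = c(0, 30, 5),
               D = c(12, 18, 6))
  mo <- structure(data.frame(label = rownames(pts), x_mm = pts[, 1L],
                             y_mm = pts[, 2L], z_mm = pts[, 3L]),
                  class = c("tenten_montage", "data.frame"))
  trip <- choose_neighbors(c(0, 19, 6), mo, M = c(0, 0, 0))
  expect_setequal(trip, c("B", "A", "D"))
})

test_that("decompose solves the three-vector system exactly", {
  M <- c(1, 2, 3)
  L1 <- c(10, 0, 0); L2 <- c(0, 12, 0); L3 <- c(0, 0, 9)
  expect_equal(decompose(L1, M, L1, L2, L3)$a, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(decompose(M, M, L1, L2, L3)$a, c(0, 0, 0), tolerance = 1e-12)

  set.seed(41)
  for (i in 1:10) {
    cp <- rnorm(3, sd = 40)
    co <- decompose(cp, M, L1, L2, L3)
    # dense-solve oracle via explicit matrix inverse
    A <- cbind(L1 - M, L2 - M, L3 - M)
    expect_equal(co$a, as.numeric(solve(A) %*% (cp - M)), tolerance = 1e-10)
    expect_lt(co$residual, 1e-9)
    # round trip through recompose in the same space
    expect_equal(recompose(co, M, L1, L2, L3), cp, tolerance = 1e-9)
  }
  expect_error(decompose(c(1, 1, 1), M, L1, 2 * L1 - M, 3 * L1 - 2 * M),
               "singular")
})

test_that("recompose is linear in the template geometry", {
  M <- c(0, 0, 0)
  L <- list(c(8, 1, 0), c(-2, 9, 1), c(0, 3, 7))
  cp <- c(2, 3, 4)
  co <- decompose(cp, M, L[[1]], L[[2]], L[[3]])
  # template scaled x2 about M doubles the offset
  expect_equal(recompose(co, M, 2 * L[[1]], 2 * L[[2]], 2 * L[[3]]),
               2 * cp, tolerance = 1e-9)
  # direct formula evaluation oracle on a random template
  set.seed(51)
  Mt <- rnorm(3); Lt <- replicate(3, rnorm(3, sd = 10), simplify = FALSE)
  got <- recompose(co, Mt, Lt[[1]], Lt[[2]], Lt[[3]])
  want <- Mt + co$a[1] * (Lt[[1]] - Mt) + co$a[2] * (Lt[[2]] - Mt) +
    co$a[3] * (Lt[[3]] - Mt)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("back-projection extends the midpoint ray to the scalp", {
  m <- sphere_mesh(64L, 32L, radius = 90)
  Mt <- c(0, 0, 0)
  p <- backproject_to_scalp(c(30, 20, 10), Mt, m)
  expect_equal(craniocorr:::vnorm(p), 90, tolerance = 0.3)
  expect_equal(craniocorr:::unitize(as.numeric(p)),
               craniocorr:::unitize(c(30, 20, 10)), tolerance = 1e-6)
  # a point on the scalp keeps s = 1
  on <- closest_point_on_mesh(m, c(90, 0, 0))$point
  p2 <- backproject_to_scalp(on, Mt, m)
  expect_equal(attr(p2, "scale"), 1, tolerance = 1e-6)
  expect_error(backproject_to_scalp(Mt, Mt, m), "midpoint")
})

test_that("transferring a subject onto itself is the identity", {
  s <- make_subject(growth_model(), 12, subject_seed = 61,
                    mesh_resolution = c(48L, 24L))
  mo <- place_montage(s$scalp, s$fiducials, "10-10")
  tr <- transfer_cohort(list(s), stats::setNames(list(mo), s$id),
                        template_id = s$id, template = s)
  Ms <- (s$fiducials["AL", ] + s$fiducials["AR", ]) / 2
  for (i in seq_len(nrow(tr))) {
    cp <- unlist(s$landmarks[s$landmarks$label == tr$label[i] &
                               s$landmarks$hemisphere == tr$hemisphere[i],
                             c("x_mm", "y_mm", "z_mm")])
    expect_equal(c(tr$xt_mm[i], tr$yt_mm[i], tr$zt_mm[i]),
                 unname(cp), tolerance = 1e-8)
    own <- backproject_to_scalp(cp, Ms, s$scalp)
    expect_equal(c(tr$xs_mm[i], tr$ys_mm[i], tr$zs_mm[i]),
                 unname(as.numeric(own)), tolerance = 1e-8)
  }
})

test_that("the transfer is equivariant under rigid motion of the template", {
  co <- small_mesh_cohort(n = 3L, seed = 71L)
  ids <- names(cohort_ages(co))
  mos <- lapply(co$subjects, function(s)
    place_montage(s$scalp, s$fiducials, "10-10"))
  names(mos) <- ids
  # keep the template out of the source set so only its template-side
  # geometry (scalp, fiducials, montage) is moved
  sources <- co$subjects[-2L]
  tr <- transfer_cohort(sources, mos, template_id = ids[2L],
                        template = co$subjects[[2L]])

  # rigidly move the template subject (mesh, fiducials, montage)
  set.seed(72)
  R <- random_rotation(); shift <- c(12, -8, 5)
  tmpl <- co$subjects[[2L]]
  tmpl$scalp <- triangle_mesh(tmpl$scalp$vertices %*% t(R) +
                                matrix(shift, nrow(tmpl$scalp$vertices), 3L,
                                       byrow = TRUE), tmpl$scalp$faces)
  tmpl$fiducials <- tmpl$fiducials %*% t(R) +
    matrix(shift, 4L, 3L, byrow = TRUE)
  mo2 <- mos
  m2 <- mos[[2L]]
  pts <- montage_matrix(m2) %*% t(R) + matrix(shift, nrow(m2), 3L,
                                              byrow = TRUE)
  m2$x_mm <- pts[, 1L]; m2$y_mm <- pts[, 2L]; m2$z_mm <- pts[, 3L]
  mo2[[2L]] <- m2
  tr2 <- transfer_cohort(sources, mo2, template_id = ids[2L],
                         template = tmpl)

  moved <- as.matrix(tr[, c("xs_mm", "ys_mm", "zs_mm")]) %*% t(R) +
    matrix(shift, nrow(tr), 3L, byrow = TRUE)
  expect_lt(max(abs(as.matrix(tr2[, c("xs_mm", "ys_mm", "zs_mm")]) - moved)),
            1e-6)
})

test_that("dispersion statistics follow the declared conventions", {
  # identical points: everything zero
  df <- data.frame(label = 1L, hemisphere = "L",
                   xs_mm = rep(3, 5), ys_mm = rep(4, 5), zs_mm = rep(5, 5))
  d0 <- dispersion(df)
  expect_equal(d0$median, 0)
  expect_equal(d0$whisker_hi, 0)

  # distances 1..9 arranged on a line around their centroid
  set.seed(81)
  x <- c(-(9:1), 9:1)  # centroid 0, distances twice 1..9
  df2 <- data.frame(label = 2L, hemisphere = "R", xs_mm = x,
                    ys_mm = 0, zs_mm = 0)
  d2 <- dispersion(df2)
  expect_equal(d2$median, 5)

  # sort-based quartile/whisker oracle on random clouds
  for (i in 1:5) {
    P <- matrix(rnorm(60, sd = 8), 20L, 3L)
    df3 <- data.frame(label = 3L, hemisphere = "L", xs_mm = P[, 1L],
                      ys_mm = P[, 2L], zs_mm = P[, 3L])
    d3 <- dispersion(df3)
    dist <- sqrt(rowSums(sweep(P, 2L, colMeans(P))^2))
    q <- stats::quantile(dist, c(0.25, 0.5, 0.75), type = 7L, names = FALSE)
    expect_equal(c(d3$q1, d3$median, d3$q3), q)
    iqr <- q[3L] - q[1L]
    expect_equal(d3$whisker_hi, max(dist[dist <= q[3L] + 1.5 * iqr]))
    expect_equal(d3$whisker_lo, min(dist[dist >= q[1L] - 1.5 * iqr]))
  }
})

test_that("dispersion grows about linearly with landmark noise", {
  meds <- vapply(c(1, 2), function(sig) {
    co <- make_cohort(growth_model(noise_sigma = sig, individual_cv = 0,
                                   drift = zero_drifts()),
                      n = 4L, seed = 91L, mesh_resolution = c(48L, 24L))
    ids <- names(cohort_ages(co))
    mos <- lapply(co$subjects, function(s)
      place_montage(s$scalp, s$fiducials, "10-10"))
    names(mos) <- ids
    tr <- transfer_cohort(co, mos, template_id = ids[2L])
    stats::median(dispersion(tr)$median)
  }, 0)
  expect_gt(meds[2L] / meds[1L], 1.4)
  expect_lt(meds[2L] / meds[1L], 2.6)
})
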