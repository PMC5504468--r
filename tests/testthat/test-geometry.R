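# AC-PC frame construction ---------------------------------------------------

test_that("acpc_align builds the stereotactic frame", {
  # already aligned input: identity
  tr <- acpc_align(NULL, ac = c(0, 10, 0), pc = c(0, -10, 0),
                   mid_sagittal = c(0, 0, 50))
  expect_equal(tr$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tr$origin, c(0, 0, 0))

  # Gram-Schmidt oracle for a rotated frame: AC on the x-axis must map to +y
  tr2 <- acpc_align(NULL, ac = c(10, 0, 0), pc = c(-10, 0, 0),
                    mid_sagittal = c(0, 0, 50))
  expect_equal(apply_acpc(tr2, c(10, 0, 0)), c(0, 10, 0), tolerance = 1e-12)
  expect_equal(det(tr2$rotation), 1, tolerance = 1e-12)

  # degenerate inputs
  expect_error(acpc_align(NULL, c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
               "degenerate")
  expect_error(acpc_align(NULL, c(0, 10, 0), c(0, -10, 0), c(0, 5, 0)),
               "degenerate")
})

test_that("acpc_align is invariant to rigid pre-transforms", {
  set.seed(42)
  pts <- matrix(rnorm(30, sd = 20), 10L, 3L)
  ac <- c(1, 12, 3); pc <- c(-1, -11, 2); mid <- c(0.5, 1, 60)
  ref <- acpc_align(pts, ac, pc, mid)$points
  for (i in 1:5) {
    R <- random_rotation()
    shift <- rnorm(3, sd = 50)
    mov <- function(p) {
      if (is.null(dim(p))) as.numeric(R %*% p + shift)
      else t(apply(p, 1L, function(q) R %*% q + shift))
    }
    out <- acpc_align(mov(pts), mov(ac), mov(pc), mov(mid))$points
    expect_lt(max(abs(out - ref)), 1e-9)
  }
})

# plane sections and arcs ----------------------------------------------------

test_that("plane_section_arc recovers great circles on a sphere", {
  m <- sphere_mesh(120L, 60L)
  arc <- plane_section_arc(m, c(0, 0, 1), c(0, 0, -1), c(1, 0, 0))
  expect_lt(abs(arc_length(arc) - pi) / pi, 0.01)
  # chosen sub-arc passes near `third`, not the opposite side
  apex <- point_at_fraction(arc, 0.5)
  expect_lt(craniocorr:::vnorm(apex - c(1, 0, 0)), 2 * median_edge_length(m))

  expect_error(plane_section_arc(m, c(0, 0, 1), c(0, 0, 1), c(1, 0, 0)),
               "zero-length")
  expect_error(plane_section_arc(m, c(0, 0, 1), c(0, 0, -1), c(0, 0, 0)),
               "collinear")
})

test_that("section arc length matches an independent triangle-slicing oracle", {
  m <- ellipsoid_mesh(c(1.3, 1.7, 1.0), 48L, 24L)
  a <- craniocorr:::surface_points(matrix(c(0.1, 0.9, 0.4), 1L),
                                   c(1.3, 1.7, 1.0), 2)[1L, ]
  b <- craniocorr:::surface_points(matrix(c(-0.2, -0.8, 0.5), 1L),
                                   c(1.3, 1.7, 1.0), 2)[1L, ]
  third <- c(0.07, 0.13, 1.21)  # generic: no mesh vertex on the plane
  # snap anchors onto mesh
  a <- closest_point_on_mesh(m, a)$point
  b <- closest_point_on_mesh(m, b)$point
  arc <- plane_section_arc(m, a, b, third)

  # oracle: slice every triangle independently, sum chained segment lengths
  n <- craniocorr:::cross3(matrix(b - a, 1L), matrix(third - a, 1L))[1L, ]
  n <- n / sqrt(sum(n^2))
  off <- sum(n * a)
  expect_gt(min(abs(as.numeric(m$vertices %*% n) - off)), 1e-9)
  seg_len_total <- 0
  segs <- list()
  for (fi in seq_len(nrow(m$faces))) {
    tri <- m$vertices[m$faces[fi, ], ]
    d <- as.numeric(tri %*% n) - off
    if (all(d > 0) || all(d < 0)) next
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      if (sign(d[e[1]]) != sign(d[e[2]])) {
        t <- d[e[1]] / (d[e[1]] - d[e[2]])
        pts[[length(pts) + 1L]] <- tri[e[1], ] + t * (tri[e[2], ] - tri[e[1], ])
      }
    }
    if (length(pts) == 2L)
      segs[[length(segs) + 1L]] <- c(pts[[1]], pts[[2]])
  }
  seg_mat <- do.call(rbind, segs)
  total_section <- sum(sqrt(rowSums((seg_mat[, 1:3] - seg_mat[, 4:6])^2)))
  # chained section length equals the exhaustive per-triangle total
  loops <- craniocorr:::section_polylines(m, n, off)
  chained <- sum(vapply(loops, function(L) {
    P <- if (L$closed) rbind(L$pts, L$pts[1L, ]) else L$pts
    sum(sqrt(rowSums(diff(P)^2)))
  }, 0))
  expect_lt(abs(chained - total_section) / total_section, 1e-6)
  # and the extracted a-b arc is a sub-arc of it
  expect_lte(arc_length(arc), chained + 1e-9)
  expect_lt(craniocorr:::vnorm(arc$endpoints[1L, ] - a),
            median_edge_length(m))
  expect_lt(craniocorr:::vnorm(arc$endpoints[2L, ] - b),
            median_edge_length(m))
})

test_that("section error halves as the mesh is refined", {
  errs <- vapply(c(30L, 60L, 120L), function(nt) {
    m <- sphere_mesh(nt, nt / 2L)
    arc <- plane_section_arc(m, c(0, 0, 1), c(0, 0, -1), c(1, 0, 0))
    abs(arc_length(arc) - pi)
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3L], errs[1L] / 3)
})

test_that("point_at_fraction honors the cumulative-length oracle", {
  arc <- plane_section_arc(sphere_mesh(), c(0, 0, 1), c(0, 0, -1), c(1, 0, 0))
  expect_equal(point_at_fraction(arc, 0), arc$polyline[1L, ])
  # f = 0.5 on a semicircle: the apex, by symmetry
  expect_lt(craniocorr:::vnorm(point_at_fraction(arc, 0.5) - c(1, 0, 0)), 0.07)

  # random polyline: prefix length / total = f exactly
  set.seed(7)
  P <- apply(matrix(rnorm(60), 20L, 3L), 2L, cumsum)
  rarc <- craniocorr:::make_surface_arc(P)
  for (f in c(0.37, 0.11, 0.93)) {
    p <- point_at_fraction(rarc, f)
    # oracle: cumulative sums up to the containing segment
    seg <- sqrt(rowSums(diff(P)^2))
    cum <- c(0, cumsum(seg))
    target <- f * sum(seg)
    i <- findInterval(target, cum, rightmost.closed = TRUE)
    prefix <- cum[i] + craniocorr:::vnorm(p - P[i, ])
    expect_equal(prefix / sum(seg), f, tolerance = 1e-9)
  }
  expect_error(point_at_fraction(rarc, 1.2), "fraction")
  expect_error(point_at_fraction(rarc, -0.1), "fraction")
})

# ray casting ----------------------------------------------------------------

test_that("ray_surface_intersection returns the outermost crossing", {
  m <- sphere_mesh(64L, 32L, radius = 2)
  for (dir in list(c(1, 0, 0), c(0.3, 0.5, 0.2), c(-1, -1, -1))) {
    hit <- ray_surface_intersection(m, c(0, 0, 0), dir)
    expect_equal(hit$t, 2, tolerance = 0.01)
  }
  expect_error(ray_surface_intersection(m, c(5, 0, 0), c(1, 0, 0)), "miss")
  expect_error(ray_surface_intersection(m, c(0, 0, 0), c(0, 0, 0)), "nonzero")
})

test_that("ray casting matches a per-triangle scan oracle", {
  m <- ellipsoid_mesh(c(1.1, 1.5, 0.9), 40L, 20L)
  set.seed(13)
  for (rep in 1:10) {
    o <- runif(3, -0.3, 0.3)
    dir <- craniocorr:::unitize(rnorm(3))
    hit <- ray_surface_intersection(m, o, dir)
    # oracle: solve the plane equation per face, test barycentrics
    best <- -Inf
    for (fi in seq_len(nrow(m$faces))) {
      tri <- m$vertices[m$faces[fi, ], ]
      e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
      nrm <- craniocorr:::cross3(matrix(e1, 1), matrix(e2, 1))[1, ]
      denom <- sum(nrm * dir)
      if (abs(denom) < 1e-12) next
      t <- sum(nrm * (tri[1, ] - o)) / denom
      if (t <= 1e-9) next
      p <- o + t * dir
      # barycentric membership via normal-projected areas
      w <- c(sum(craniocorr:::cross3(matrix(tri[3, ] - tri[2, ], 1),
                                     matrix(p - tri[2, ], 1))[1, ] * nrm),
             sum(craniocorr:::cross3(matrix(tri[1, ] - tri[3, ], 1),
                                     matrix(p - tri[3, ], 1))[1, ] * nrm),
             sum(craniocorr:::cross3(matrix(e1, 1),
                                     matrix(p - tri[1, ], 1))[1, ] * nrm))
      if (all(w >= -1e-9 * sum(nrm * nrm))) best <- max(best, t)
    }
    expect_equal(hit$t, best, tolerance = 1e-9)
  }
})

# plane projections ----------------------------------------------------------

test_that("project zeroes the expected coordinate", {
  expect_equal(project(c(3, 4, 5), "sagittal"), c(0, 4, 5))
  expect_equal(project(c(3, 4, 5), "coronal"), c(3, 0, 5))
  # x-only differences vanish under sagittal projection
  a <- project(c(3, 4, 5), "sagittal"); b <- project(c(-8, 4, 5), "sagittal")
  expect_equal(craniocorr:::vnorm(a - b), 0)
  m <- matrix(1:6, 2L, 3L)
  expect_equal(project(m, "coronal")[, 2L], c(0, 0))
})
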