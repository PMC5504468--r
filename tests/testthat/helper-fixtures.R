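# Shared fixtures: analytic meshes, equatorial fiducials and the
# closed-form spherical montage oracle used against the mesh construction.

sphere_mesh <- function(n_theta = 96L, n_phi = 48L, radius = 1) {
  m <- craniocorr:::unit_sphere_mesh(n_theta, n_phi)
  triangle_mesh(m$vertices * radius, m$faces)
}

ellipsoid_mesh <- function(semi = c(1.2, 1.6, 1.0), n_theta = 80L, n_phi = 40L) {
  m <- craniocorr:::unit_sphere_mesh(n_theta, n_phi)
  triangle_mesh(sweep(m$vertices, 2L, semi, "*"), m$faces)
}

sphere_fiducials <- function(radius = 1) {
  rbind(Nz = c(0, radius, 0), Iz = c(0, -radius, 0),
        AL = c(-radius, 0, 0), AR = c(radius, 0, 0))
}

# closed-form montage positions on the unit sphere with equatorial
# fiducials at 90 degree spacing: midline/coronal positions lie on great
# circles; ring positions on the z = sin(0.1*pi) circle; transverse-row
# positions on the circle through their three anchors. Independent of the
# mesh pipeline (pure trigonometry).
spherical_montage_oracle <- function(system = "10-20") {
  mid <- function(f) c(0, cos(f * pi), sin(f * pi))          # Nz -> Iz
  cor <- function(f) c(-cos(f * pi), 0, sin(f * pi))         # AL -> AR
  zr <- sin(0.1 * pi); rr <- cos(0.1 * pi)
  ring <- function(g) {                                       # from Fpz, left first
    ang <- pi / 2 + g * 2 * pi
    c(rr * cos(ang), rr * sin(ang), zr)
  }
  # circle through three points on the sphere, parametrized by angle from
  # point a towards b passing c at equal-arc fractions
  row_curve <- function(a, c3, b) {
    ctr_n <- craniocorr:::unitize(craniocorr:::cross3(
      matrix(b - a, 1), matrix(c3 - a, 1))[1, ])
    ctr <- sum(ctr_n * a) * ctr_n                # circle center
    u <- craniocorr:::unitize(a - ctr)
    w <- craniocorr:::cross3(matrix(ctr_n, 1), matrix(u, 1))[1, ]
    rad <- sqrt(sum((a - ctr)^2))
    angle_of <- function(p) atan2(sum((p - ctr) * w), sum((p - ctr) * u))
    th_b <- angle_of(b); th_c <- angle_of(c3)
    # traverse towards b the way that passes c
    if (th_b < 0) th_b <- th_b + 2 * pi
    if (th_c < 0) th_c <- th_c + 2 * pi
    dir <- if (th_c < th_b) 1 else -1
    span <- if (dir == 1) th_b else 2 * pi - th_b
    function(f) {
      th <- dir * f * span
      ctr + rad * (cos(th) * u + sin(th) * w)
    }
  }
  pos <- list(Nz = mid(0), Iz = mid(1), AL = cor(0), AR = cor(1))
  mids <- c(Fpz = .1, AFz = .2, Fz = .3, FCz = .4, Cz = .5, CPz = .6,
            Pz = .7, POz = .8, Oz = .9)
  for (nm in names(mids)) pos[[nm]] <- mid(mids[[nm]])
  cors <- c(T3 = .1, C5 = .2, C3 = .3, C1 = .4, C2 = .6, C4 = .7,
            C6 = .8, T4 = .9)
  for (nm in names(cors)) pos[[nm]] <- cor(cors[[nm]])
  rings <- c(Fp1 = .05, AF7 = .1, F7 = .15, FT7 = .2, TP7 = .3, T5 = .35,
             PO7 = .4, O1 = .45, O2 = .55, PO8 = .6, T6 = .65, TP8 = .7,
             FT8 = .8, F8 = .85, AF8 = .9, Fp2 = .95)
  for (nm in names(rings)) pos[[nm]] <- ring(rings[[nm]])
  rows <- list(
    F = list("F7", "Fz", "F8",
             c(F5 = 1, F3 = 2, F1 = 3, F2 = 5, F4 = 6, F6 = 7) / 8),
    FC = list("FT7", "FCz", "FT8",
              c(FC5 = 1, FC3 = 2, FC1 = 3, FC2 = 5, FC4 = 6, FC6 = 7) / 8),
    CP = list("TP7", "CPz", "TP8",
              c(CP5 = 1, CP3 = 2, CP1 = 3, CP2 = 5, CP4 = 6, CP6 = 7) / 8),
    P = list("T5", "Pz", "T6",
             c(P5 = 1, P3 = 2, P1 = 3, P2 = 5, P4 = 6, P6 = 7) / 8),
    AF = list("AF7", "AFz", "AF8", c(AF3 = 1, AF4 = 3) / 4),
    PO = list("PO7", "POz", "PO8", c(PO3 = 1, PO4 = 3) / 4))
  for (rw in rows) {
    crv <- row_curve(pos[[rw[[1]]]], pos[[rw[[2]]]], pos[[rw[[3]]]])
    for (nm in names(rw[[4]])) pos[[nm]] <- crv(rw[[4]][[nm]])
  }
  m <- do.call(rbind, pos)
  if (system == "10-20") {
    keep <- c("Nz", "Iz", "AL", "AR", "Fpz", "Fz", "Cz", "Pz", "Oz",
              "T3", "C3", "C4", "T4", "Fp1", "Fp2", "F7", "F8", "T5",
              "T6", "O1", "O2", "F3", "F4", "P3", "P4")
    m <- m[keep, ]
  }
  m
}

# random proper rotation (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9L), 3L))
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# shape-preserving (proportional growth) model used for null
# constructions: semi-axes scale by the same factor at every age, so all
# shape statistics are exactly age-invariant
null_model <- function(noise_sigma = 2.16, rate = 0.012, ...) {
  base <- c(width = 50, length = 58, height = 44)
  growth_model(base_semiaxes = base, growth = base * rate,
               drift = zero_drifts(), noise_sigma = noise_sigma,
               individual_cv = 0, ...)
}

# small synthetic head cohort with meshes at reduced resolution
small_mesh_cohort <- function(n = 4L, seed = 7L, model = growth_model()) {
  make_cohort(model, n = n, seed = seed, mesh_resolution = c(48L, 24L))
}
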