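#' Growth model for the synthetic infant cohort
#'
#' Parameterizes a cohort of superellipsoid infant heads whose brain
#' semi-axes grow linearly with age, with growth most prominent along the
#' anterior-posterior axis (length), then height, then width — the ordering
#' reported for infant brain growth in the first two years. Selected
#' cortical landmarks additionally drift along the surface with age
#' (anterior drifts around the precentral/intraparietal region, a dorsal
#' drift of the calcarine landmark, an optional right-lateralized ventral
#' drift), and every landmark carries isotropic Gaussian localization noise
#' emulating inter-rater variability.
#'
#' The default noise sigma of 2.16 mm is chosen so that the mean 3-D
#' distance between two independent rater realizations of a landmark,
#' `4 * sigma / sqrt(pi)`, is about 4.87 mm.
#'
#' Absolute head dimensions are configurable assumptions (defaults give a
#' 12-month brain length of about 138 mm), not literature values.
#'
#' @param base_semiaxes named numeric: brain semi-axes `width` (x), `length`
#'   (y), `height` (z) in mm at age 0 months.
#' @param growth named numeric: per-axis semi-axis growth slopes, mm/month.
#' @param scalp_offset scalp-to-brain surface offset in mm.
#' @param individual_cv coefficient of variation of per-subject
#'   multiplicative semi-axis factors (individual anatomy, independent of
#'   age); set to 0 for a cohort that differs only by age.
#' @param exponent superellipsoid squareness exponent (2 = ellipsoid).
#' @param drift data.frame of per-landmark drift rates, see
#'   [default_drifts()]; use `zero_drifts()` for a drift-free model.
#' @param noise_sigma landmark localization noise SD per coordinate, mm.
#' @param seed integer seed recorded with the model.
#' @return an object of class `growth_model`.
#' @export
growth_model <- function(base_semiaxes = c(width = 50, length = 58, height = 44),
                         growth = c(width = 0.35, length = 0.90, height = 0.55),
                         scalp_offset = 8,
                         individual_cv = 0.03,
                         exponent = 2.5,
                         drift = default_drifts(),
                         noise_sigma = 2.16,
                         seed = 1L) {
  nm <- c("width", "length", "height")
  base_semiaxes <- base_semiaxes[nm]
  growth <- growth[nm]
  if (anyNA(base_semiaxes) || anyNA(growth))
    stop("base_semiaxes and growth must name width, length and height")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(base_semiaxes <= 0) || any(base_semiaxes + 24 * growth <= 0))
    stop("semi-axes must stay positive over 0-24 months")
  if (scalp_offset <= 0) stop("scalp_offset must be positive")
  if (individual_cv < 0) stop("individual_cv must be >= 0")
  structure(list(base_semiaxes = base_semiaxes, growth = growth,
                 scalp_offset = scalp_offset, individual_cv = individual_cv,
                 exponent = exponent, drift = drift,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat("growth_model (superellipsoid infant head)\n")
  cat(sprintf("  semi-axes at 0 mo: %.1f x %.1f x %.1f mm (w x l x h)\n",
              x$base_semiaxes[1L], x$base_semiaxes[2L], x$base_semiaxes[3L]))
  cat(sprintf("  growth slopes:     %.2f / %.2f / %.2f mm/mo\n",
              x$growth[1L], x$growth[2L], x$growth[3L]))
  cat(sprintf("  scalp offset %.1f mm, noise sigma %.2f mm, %d drifting landmarks\n",
              x$scalp_offset, x$noise_sigma, nrow(x$drift)))
  invisible(x)
}

#' Default and null landmark drift tables
#'
#' Age-dependent surface drifts injected into the generator: anterior
#' drifts of the precentral-region junction landmarks (8, 9, 10) and the
#' postcentral/intraparietal junction (12), a dorsal drift of the calcarine
#' landmark (14), and a right-only ventral drift of the inferior temporal
#' sulcus landmark (18). Rates (mm/month) are calibrated so the Table-1
#' style ratio-age correlations reach roughly |r| 0.6-0.7 over a 16-subject
#' cohort at the default noise level.
#'
#' @return data.frame with columns `label`, `hemisphere` (`"B"` = both),
#'   `direction` (`anterior`, `dorsal`, `ventral`), `rate` (mm/month).
#' @export
default_drifts <- function() {
  data.frame(
    label = c(8L, 9L, 10L, 12L, 14L, 18L),
    hemisphere = c("B", "B", "B", "B", "B", "R"),
    direction = c("anterior", "anterior", "anterior", "anterior",
                  "dorsal", "ventral"),
    rate = c(0.55, 0.55, 0.55, 0.55, 0.5, 0.5),
    stringsAsFactors = FALSE)
}

#' @rdname default_drifts
#' @export
zero_drifts <- function() {
  d <- default_drifts()[0, , drop = FALSE]
  d
}

#' Expected inter-rater landmark distance under the noise model
#'
#' Mean 3-D distance between two independent isotropic Gaussian
#' realizations of the same landmark: `4 * sigma / sqrt(pi)`.
#'
#' @param sigma per-coordinate noise SD in mm.
#' @return expected distance in mm.
#' @export
expected_interrater_distance <- function(sigma) 4 * sigma / sqrt(pi)

#' Precision threshold from inter-rater statistics
#'
#' The agreement threshold used with rated landmarks: one SD above the mean
#' inter-rater coordinate distance.
#'
#' @param mean,sd mean and SD of the inter-rater distance, mm.
#' @return threshold in mm.
#' @export
precision_threshold <- function(mean, sd) mean + sd

# ---- superellipsoid geometry ------------------------------------------------

# radius along unit direction u for sum(|x_i/s_i|^p) = 1
superellipsoid_radius <- function(u, semi, p) {
  (rowSums((abs(u) / matrix(semi, nrow(u), 3L, byrow = TRUE))^p))^(-1 / p)
}

surface_points <- function(dirs, semi, p) {
  dirs <- dirs / sqrt(rowSums(dirs^2))
  dirs * superellipsoid_radius(dirs, semi, p)
}

surface_normal <- function(x, semi, p) {
  g <- p * abs(x / semi)^(p - 1) * sign(x) / semi
  unitize(g)
}

# unit tangent at surface point x in the direction of global vector g
surface_tangent <- function(x, semi, p, g) {
  n <- surface_normal(x, semi, p)
  t <- g - sum(g * n) * n
  if (vnorm(t) < 1e-9) return(c(0, 0, 0))
  t / vnorm(t)
}

# lateral surface x-coordinate at a given (y, z) cross-section position
lateral_x <- function(y, z, semi, p) {
  rem <- 1 - abs(y / semi[2L])^p - abs(z / semi[3L])^p
  semi[1L] * pmax(rem, 0)^(1 / p)
}

superellipsoid_mesh <- function(semi, p, n_theta = 72L, n_phi = 36L) {
  sph <- unit_sphere_mesh(n_theta, n_phi)
  triangle_mesh(surface_points(sph$vertices, semi, p), sph$faces)
}

# ---- landmark vocabulary ----------------------------------------------------

# parametric (unit-direction) locations of the 20 per-hemisphere landmarks,
# left hemisphere (x < 0); the right hemisphere mirrors x. Labels 1-6 are
# extremal points, 7-15 and 20 macroanatomical structures, 16-19 dependent
# landmarks on the coronal slice of landmark 11 (defined by z-fractions).
landmark_directions <- function() {
  m <- rbind(
    "1"  = c(-0.10,  0.00,  0.995),  # vertex
    "2"  = c(-0.25,  0.95,  0.15),   # frontal pole
    "3"  = c(-0.55,  0.75, -0.35),   # temporal pole
    "4"  = c(-0.35,  0.05, -0.93),   # base of the brain
    "5"  = c(-0.20, -0.97,  0.10),   # occipital pole
    "6"  = c(-0.995, -0.05, 0.00),   # leftmost/rightmost point
    "7"  = c(-0.25, -0.05,  0.96),   # upper end of the central sulcus
    "8"  = c(-0.45,  0.45,  0.77),   # SFS x precentral junction
    "9"  = c(-0.80,  0.45,  0.30),   # IFS x precentral junction
    "10" = c(-0.90,  0.35, -0.10),   # ascending ramus of the Sylvian fissure
    "11" = c(-0.97,  0.05,  0.10),   # CS tip
    "12" = c(-0.55, -0.35,  0.76),   # postcentral x intraparietal junction
    "13" = c(-0.60, -0.70, -0.30),   # preoccipital notch
    "14" = c(-0.30, -0.92, -0.15),   # calcarine fissure
    "15" = c(-0.20, -0.75,  0.63),   # parieto-occipital sulcus
    "20" = c(-0.85, -0.30,  0.25))   # posterior ascending branch, Sylvian f.
  m / sqrt(rowSums(m^2))
}

# z positions of the dependent landmarks 16-19 as fractions of the height
# semi-axis (Sylvian fissure, STS, ITS, ventral temporal edge)
dependent_z_fractions <- function() {
  c("16" = 0.10, "17" = -0.25, "18" = -0.55, "19" = -0.85)
}

drift_vector <- function(direction) {
  switch(direction,
         anterior = c(0, 1, 0),
         dorsal = c(0, 0, 1),
         ventral = c(0, 0, -1),
         stop("unknown drift direction: ", direction))
}

# ---- subject and cohort generation -----------------------------------------

#' Generate one synthetic infant subject
#'
#' Builds a superellipsoid brain with age-scaled semi-axes, a scalp surface
#' offset outward from it, the four cranial fiducials at the scalp's
#' parametric extremes, and the 20-per-hemisphere landmark set with the
#' model's age drifts and localization noise. Landmarks 16-19 are dependent
#' landmarks computed on the coronal slice through landmark 11.
#'
#' @param model a [growth_model()].
#' @param age_months age in months, in \[0, 30\].
#' @param subject_seed integer seed making the subject reproducible; if
#'   `NULL` the current RNG stream is used.
#' @param subject_id subject identifier string.
#' @param meshes build the brain/scalp triangle meshes (set `FALSE` for
#'   landmark-only simulations, e.g. large correlation studies).
#' @param mesh_resolution `c(n_theta, n_phi)` mesh resolution.
#' @return an object of class `synthetic_subject`: `id`, `age_months`,
#'   `brain`, `scalp` (meshes or NULL), `fiducials` (4 x 3 matrix with rows
#'   Nz, Iz, AL, AR), `landmarks` (data.frame), `ground_truth` (noise-free
#'   landmark table plus drift magnitudes).
#' @export
make_subject <- function(model, age_months, subject_seed = NULL,
                         subject_id = sprintf("S%02.0f", age_months),
                         meshes = TRUE, mesh_resolution = c(72L, 36L)) {
  if (age_months < 0 || age_months > 30)
    stop("age_months must be in [0, 30]")
  if (!is.null(subject_seed)) set.seed(as.integer(subject_seed))
  p <- model$exponent
  # individual anatomy: per-subject multiplicative semi-axis factors,
  # drawn first so the noise stream is unaffected by their presence only
  # when cv = 0
  indiv <- if (model$individual_cv > 0)
    exp(stats::rnorm(3L, 0, model$individual_cv)) else rep(1, 3L)
  semi <- as.numeric(model$base_semiaxes + model$growth * age_months) * indiv
  semi_scalp <- semi + model$scalp_offset

  dirs <- landmark_directions()
  zfrac <- dependent_z_fractions()
  sigma <- model$noise_sigma

  one_hemi <- function(hemi) {
    d <- dirs
    if (hemi == "R") d[, 1L] <- -d[, 1L]
    pts <- surface_points(d, semi, p)
    rownames(pts) <- rownames(d)
    # age drifts along the surface tangent
    driftmag <- stats::setNames(numeric(nrow(pts)), rownames(pts))
    for (i in seq_len(nrow(model$drift))) {
      dr <- model$drift[i, ]
      if (!(dr$hemisphere %in% c("B", hemi))) next
      lab <- as.character(dr$label)
      if (!lab %in% rownames(pts)) next
      tv <- surface_tangent(pts[lab, ], semi, p, drift_vector(dr$direction))
      pts[lab, ] <- pts[lab, ] + dr$rate * age_months * tv
      driftmag[lab] <- dr$rate * age_months
    }
    list(pts = pts, driftmag = driftmag)
  }

  hemis <- list(L = one_hemi("L"), R = one_hemi("R"))

  build_table <- function(noisy) {
    rows <- list()
    for (hemi in c("L", "R")) {
      pts <- hemis[[hemi]]$pts
      noise <- if (noisy && sigma > 0)
        matrix(stats::rnorm(length(pts), sd = sigma), nrow(pts), 3L)
      else matrix(0, nrow(pts), 3L)
      obs <- pts + noise
      # dependent landmarks 16-19 on the coronal slice of (observed) 11
      y11 <- obs["11", 2L]
      dep <- t(vapply(names(zfrac), function(lab) {
        z <- zfrac[[lab]] * semi[3L]
        if (lab == "18") {  # optional ventral drift, right hemisphere only
          dr <- model$drift[model$drift$label == 18L &
                              model$drift$hemisphere %in% c(hemi, "B"), ]
          if (nrow(dr) > 0L && dr$direction[1L] == "ventral")
            z <- z - dr$rate[1L] * age_months
        }
        x <- lateral_x(y11, z, semi, p) * (if (hemi == "L") -1 else 1)
        c(x, y11, z)
      }, numeric(3L)))
      depnoise <- if (noisy && sigma > 0)
        matrix(stats::rnorm(length(dep), sd = sigma), nrow(dep), 3L)
      else matrix(0, nrow(dep), 3L)
      all_pts <- rbind(obs, dep + depnoise)
      ord <- order(as.integer(rownames(all_pts)))
      all_pts <- all_pts[ord, , drop = FALSE]
      rows[[hemi]] <- data.frame(
        subject_id = subject_id, age_months = age_months,
        label = as.integer(rownames(all_pts)), hemisphere = hemi,
        x_mm = all_pts[, 1L], y_mm = all_pts[, 2L], z_mm = all_pts[, 3L],
        space = "acpc", stringsAsFactors = FALSE, row.names = NULL)
    }
    do.call(rbind, rows)
  }

  truth <- build_table(noisy = FALSE)
  landmarks <- build_table(noisy = TRUE)

  fid <- rbind(Nz = c(0, semi_scalp[2L], 0),
               Iz = c(0, -semi_scalp[2L], 0),
               AL = c(-semi_scalp[1L], 0, 0),
               AR = c(semi_scalp[1L], 0, 0))

  out <- list(id = subject_id, age_months = age_months,
              semi_axes = semi, scalp_semi_axes = semi_scalp,
              exponent = p,
              brain = NULL, scalp = NULL,
              fiducials = fid, landmarks = landmarks,
              ground_truth = list(
                landmarks = truth,
                drift_mm = c(L = list(hemis$L$driftmag),
                             R = list(hemis$R$driftmag))))
  if (meshes) {
    out$brain <- superellipsoid_mesh(semi, p, mesh_resolution[1L],
                                     mesh_resolution[2L])
    out$scalp <- superellipsoid_mesh(semi_scalp, p, mesh_resolution[1L],
                                     mesh_resolution[2L])
  }
  structure(out, class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("synthetic_subject %s: %.1f months, brain %.0f x %.0f x %.0f mm%s\n",
              x$id, x$age_months, 2 * x$semi_axes[1L], 2 * x$semi_axes[2L],
              2 * x$semi_axes[3L],
              if (is.null(x$brain)) " (no meshes)" else ""))
  invisible(x)
}

#' Generate a synthetic infant cohort
#'
#' Ages are spread evenly (with jitter) across the range; the defaults,
#' 16 subjects aged 3-22 months, mirror a typical infant MRI cohort for
#' this kind of study.
#'
#' @inheritParams make_subject
#' @param n number of subjects (>= 3).
#' @param age_range length-2 age range in months.
#' @param seed integer root seed; defaults to the model's seed.
#' @return an object of class `synthetic_cohort` (list of subjects with
#'   the model attached).
#' @export
make_cohort <- function(model, n = 16L, age_range = c(3, 22),
                        seed = model$seed, meshes = TRUE,
                        mesh_resolution = c(72L, 36L)) {
  if (n < 3L) stop("a cohort needs at least 3 subjects")
  set.seed(as.integer(seed))
  ages <- seq(age_range[1L], age_range[2L], length.out = n)
  if (n > 1L) {
    step <- diff(age_range) / (n - 1L)
    jit <- stats::runif(n, -0.4, 0.4) * step
    ages <- pmin(age_range[2L], pmax(age_range[1L], ages + jit))
  }
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- lapply(seq_len(n), function(i) {
    make_subject(model, ages[i], subject_seed = subject_seeds[i],
                 subject_id = sprintf("S%02d", i), meshes = meshes,
                 mesh_resolution = mesh_resolution)
  })
  structure(list(subjects = subjects, model = model, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  ages <- vapply(x$subjects, `[[`, 0, "age_months")
  cat(sprintf("synthetic_cohort: %d subjects, ages %.1f-%.1f months\n",
              length(x$subjects), min(ages), max(ages)))
  invisible(x)
}

#' Stack a cohort's landmark tables
#' @param cohort a `synthetic_cohort`.
#' @param ground_truth use the noise-free tables instead of the observed ones.
#' @return one landmark data.frame for all subjects.
#' @export
cohort_landmarks <- function(cohort, ground_truth = FALSE) {
  do.call(rbind, lapply(cohort$subjects, function(s)
    if (ground_truth) s$ground_truth$landmarks else s$landmarks))
}

#' Cohort ages, named by subject
#' @param cohort a `synthetic_cohort`.
#' @return named numeric vector of ages in months.
#' @export
cohort_ages <- function(cohort) {
  stats::setNames(vapply(cohort$subjects, `[[`, 0, "age_months"),
                  vapply(cohort$subjects, `[[`, "", "id"))
}

#' Write a cohort to disk as plain-text fixture files
#'
#' Writes `landmarks.tsv` and `ground_truth.tsv` (landmark tables),
#' `fiducials.tsv`, per-subject OBJ meshes (when present) and a
#' `manifest.tsv` listing every subject. Files round-trip through
#' [read_landmarks()] / [read_mesh()] to 1e-6 mm.
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory destination directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_fixture <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_landmarks(cohort_landmarks(cohort),
                  file.path(directory, "landmarks.tsv"))
  write_landmarks(cohort_landmarks(cohort, ground_truth = TRUE),
                  file.path(directory, "ground_truth.tsv"))
  fid <- do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$id, fiducial = rownames(s$fiducials),
               x_mm = s$fiducials[, 1L], y_mm = s$fiducials[, 2L],
               z_mm = s$fiducials[, 3L], row.names = NULL)
  }))
  utils::write.table(fid, file.path(directory, "fiducials.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- do.call(rbind, lapply(cohort$subjects, function(s) {
    brain_file <- scalp_file <- NA_character_
    if (!is.null(s$brain)) {
      brain_file <- sprintf("brain_%s.obj", s$id)
      scalp_file <- sprintf("scalp_%s.obj", s$id)
      write_mesh(s$brain, file.path(directory, brain_file))
      write_mesh(s$scalp, file.path(directory, scalp_file))
    }
    data.frame(subject_id = s$id, age_months = s$age_months,
               brain_mesh = brain_file, scalp_mesh = scalp_file,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
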