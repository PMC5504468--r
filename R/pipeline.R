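#' Pipeline configuration
#'
#' Collects and validates every setting of the end-to-end analysis:
#' cohort source (a growth model for synthetic cohorts), montage system,
#' Procrustes settings, ratio specification table, transfer template and
#' the root seed. All stage randomness derives from the single seed.
#'
#' @param model a [growth_model()] describing the synthetic cohort.
#' @param n,age_range cohort size and age range in months.
#' @param system montage system, `"10-20"` or `"10-10"`.
#' @param gpa_tol,gpa_max_iter Procrustes convergence settings.
#' @param specs ratio specification table (default [ratio_specs()]).
#' @param template_id subject id used as the transfer template; default
#'   the subject nearest 12 months of age.
#' @param exclude subject ids excluded from the transfer.
#' @param outdir output directory for stage TSVs, or `NULL` to skip
#'   writing.
#' @param seed root seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(model = growth_model(), n = 16L,
                            age_range = c(3, 22), system = "10-10",
                            gpa_tol = 1e-8, gpa_max_iter = 100L,
                            specs = ratio_specs(), template_id = NULL,
                            exclude = character(), outdir = NULL,
                            seed = 1L) {
  stopifnot(inherits(model, "growth_model"))
  if (n < 3L) stop("config invalid: cohort needs at least 3 subjects")
  if (!system %in% c("10-20", "10-10")) stop("unknown montage system")
  if (!all(c("a", "b", "c", "mode") %in% names(specs)))
    stop("ratio spec table lacks required columns")
  structure(list(model = model, n = as.integer(n), age_range = age_range,
                 system = system, gpa_tol = gpa_tol,
                 gpa_max_iter = as.integer(gpa_max_iter), specs = specs,
                 template_id = template_id, exclude = exclude,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full co-development analysis pipeline
#'
#' Executes, in order: synthetic cohort generation; per-subject virtual
#' montage placement (both the configured system and the 25-point 10-20
#' set used for head shape analysis); generalized Procrustes analysis with
#' shape PCA and PC-score age regression for the cortical and head
#' configurations; the ratio-age correlation table (with lateral surface
#' adjustment of junction landmarks); transfer of all cortical landmarks
#' to the template scalp with dispersion statistics. Deterministic given
#' the config seed; when `outdir` is set every stage writes a TSV.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` with elements `cohort`,
#'   `montages`, `cortex` and `head` (each: `fit`, `pca`, `age_cor`),
#'   `topo_table`, `transfer`, `dispersion`, `nn_distances`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  cohort <- make_cohort(config$model, n = config$n,
                        age_range = config$age_range, seed = config$seed)
  ages <- cohort_ages(cohort)
  lms <- cohort_landmarks(cohort)
  ids <- names(ages)

  montages <- lapply(cohort$subjects, function(s)
    place_montage(s$scalp, s$fiducials, config$system))
  names(montages) <- ids
  montages_1020 <- if (config$system == "10-20") montages
  else {
    m <- lapply(cohort$subjects, function(s)
      place_montage(s$scalp, s$fiducials, "10-20"))
    names(m) <- ids
    m
  }

  analyse <- function(confs) {
    fit <- gpa(confs, tol = config$gpa_tol, max_iter = config$gpa_max_iter)
    p <- pca_shapes(fit)
    list(fit = fit, pca = p,
         age_cor = regress_scores_on_age(p$scores[, 1L], fit$ages))
  }
  cortex <- analyse(configurations(lms, "cortex", ages))
  head_an <- analyse(montage_configurations(montages_1020, ages))

  brains <- lapply(cohort$subjects, `[[`, "brain")
  names(brains) <- ids
  topo <- table1_analysis(lms, ages, specs = config$specs, brains = brains)

  template_id <- config$template_id
  if (is.null(template_id)) template_id <- ids[which.min(abs(ages - 12))]
  transfer <- transfer_cohort(cohort, montages, template_id,
                              exclude = config$exclude)
  disp <- dispersion(transfer)
  nn <- nearest_neighbor_distances(montages[[template_id]])

  report <- structure(
    list(cohort = cohort, montages = montages, cortex = cortex,
         head = head_an, topo_table = topo, transfer = transfer,
         dispersion = disp, nn_distances = nn,
         template_id = template_id, seed = config$seed),
    class = "pipeline_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Cranio-cerebral correspondence pipeline report\n")
  cat(sprintf("  cohort: %d subjects; seed %d; template %s\n",
              length(x$cohort$subjects), x$seed, x$template_id))
  vfc <- x$cortex$pca$variance_fractions
  vfh <- x$head$pca$variance_fractions
  first4 <- function(v) paste(sprintf("%.1f%%", 100 * v[seq_len(min(4L,
    length(v)))]), collapse = "/")
  cat(sprintf("  cortex PCA: %s; PC1-age r = %.2f (p = %.3f)\n",
              first4(vfc), x$cortex$age_cor$r, x$cortex$age_cor$p))
  cat(sprintf("  head PCA:   %s; PC1-age r = %.2f (p = %.3f)\n",
              first4(vfh), x$head$age_cor$r, x$head$age_cor$p))
  sig <- sum(x$topo_table$p < 0.05)
  cat(sprintf("  ratio table: %d rows, %d with p < 0.05\n",
              nrow(x$topo_table), sig))
  cat(sprintf("  dispersion: median of medians %.1f mm; montage NN median %.1f mm\n",
              stats::median(x$dispersion$median), stats::median(x$nn_distances)))
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) utils::write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_landmarks(cohort_landmarks(report$cohort),
                  file.path(outdir, "landmarks.tsv"))
  mo <- do.call(rbind, lapply(names(report$montages), function(id) {
    df <- as.data.frame(report$montages[[id]])
    cbind(subject_id = id, df)
  }))
  wt(mo, "montages.tsv")
  for (what in c("cortex", "head")) {
    an <- report[[what]]
    vf <- data.frame(pc = seq_along(an$pca$variance_fractions),
                     variance_fraction = an$pca$variance_fractions)
    wt(vf, sprintf("%s_variance_fractions.tsv", what))
    sc <- data.frame(subject_id = an$fit$subjects, age_months = an$fit$ages,
                     pc1_score = an$pca$scores[, 1L])
    wt(sc, sprintf("%s_pc1_scores.tsv", what))
  }
  wt(as.data.frame(report$topo_table), "ratio_age_correlations.tsv")
  wt(as.data.frame(report$transfer), "transferred_points.tsv")
  wt(as.data.frame(report$dispersion), "dispersion_stats.tsv")
  wt(data.frame(label = names(report$nn_distances),
                nn_mm = as.numeric(report$nn_distances)),
     "montage_nearest_neighbor.tsv")
  invisible(outdir)
}

#' Validate pipeline inputs
#'
#' Checks a landmark table and (optionally) meshes and fiducials for the
#' problems that break downstream stages: missing fiducials, incomplete
#' landmark labels or hemisphere coverage, non-watertight scalp meshes.
#' Reports issues instead of raising.
#'
#' @param landmarks a landmark data.frame (see [read_landmarks()]).
#' @param fiducials optional named list (by subject) of 4 x 3 fiducial
#'   matrices with rows Nz, Iz, AL, AR.
#' @param meshes optional named list (by subject) of scalp meshes.
#' @param labels the labels each subject must provide (default 1-20).
#' @return data.frame with columns `subject_id`, `severity`, `issue`;
#'   zero rows when everything is clean.
#' @export
validate_inputs <- function(landmarks, fiducials = NULL, meshes = NULL,
                            labels = 1:20) {
  issues <- list()
  note <- function(subject, severity, issue)
    issues[[length(issues) + 1L]] <<- data.frame(
      subject_id = subject, severity = severity, issue = issue,
      stringsAsFactors = FALSE)
  for (id in unique(landmarks$subject_id)) {
    sub <- landmarks[landmarks$subject_id == id, ]
    for (hemi in c("L", "R")) {
      miss <- setdiff(labels, sub$label[sub$hemisphere == hemi])
      if (length(miss) > 0L)
        note(id, "error", sprintf("hemisphere %s missing labels: %s", hemi,
                                  paste(miss, collapse = ", ")))
    }
    if (!all(is.finite(as.matrix(sub[, c("x_mm", "y_mm", "z_mm")]))))
      note(id, "error", "non-finite coordinates")
  }
  if (!is.null(fiducials)) {
    for (id in names(fiducials)) {
      miss <- setdiff(c("Nz", "Iz", "AL", "AR"), rownames(fiducials[[id]]))
      if (length(miss) > 0L)
        note(id, "error", sprintf("fiducial absent: %s",
                                  paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(meshes)) {
    for (id in names(meshes)) {
      m <- meshes[[id]]
      if (!isTRUE(m$watertight)) {
        e <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
        key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
        nb <- sum(tabulate(factor(key)) != 2L)
        note(id, "warning",
             sprintf("scalp mesh not watertight (%d boundary edges)", nb))
      }
    }
  }
  if (length(issues) == 0L)
    return(data.frame(subject_id = character(), severity = character(),
                      issue = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
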