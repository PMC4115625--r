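#' Ground truth for the group-dissociation experiment
#'
#' Two bilateral 6 mm regions planted in the default small grid
#' (16 x 16 x 12 voxels of 3 x 3 x 3.3 mm). The univariate response
#' amplitude (vocal 0.15, non-vocal 0 signal units at noise SD 1, i.e. a
#' 0.15% sustained response at baseline 100) is identical in both groups,
#' while the subject-specific multivoxel pattern amplitude differs
#' (F 0.23 vs M 0.05). At these settings the per-block beta noise is about
#' 0.54, so the multivariate class separability over a ~20-voxel sphere is
#' roughly 4 noise units for females and 1.5 for males:
#' both groups decode vocal vs non-vocal above chance, females close to
#' ceiling, males modestly -- yet the expected univariate contrast is equal
#' across groups and the subject-specific patterns average out of it, the
#' configuration in which only the multivariate track shows a group
#' difference.
#'
#' @param centers List of two (or more) region centre voxels.
#' @param radius_mm Region radius, mm.
#' @param pattern_scale Named numeric (`F`, `M`) pattern amplitudes.
#' @param vocal_amplitude Mean vocal-block amplitude, both groups.
#' @param noise_sd Noise SD.
#' @param group_sizes Named integer (`F`, `M`).
#' @return A [ground_truth_spec()] with subject-specific patterns.
#' @export
dissociation_truth <- function(centers = list(c(5L, 8L, 6L), c(12L, 8L, 6L)),
                               radius_mm = 6,
                               pattern_scale = c(F = 0.23, M = 0.05),
                               vocal_amplitude = 0.15,
                               noise_sd = 1,
                               group_sizes = c(F = 8L, M = 8L)) {
  amp <- c(vocal = vocal_amplitude, "non-vocal" = 0)
  ground_truth_spec(regions = lapply(centers, region, radius_mm = radius_mm),
                    univariate_amplitude = list(F = amp, M = amp),
                    pattern_scale = pattern_scale, noise_sd = noise_sd,
                    group_sizes = group_sizes, pattern_mode = "subject")
}

#' Pipeline configuration
#'
#' Bundles every stage's specification. The default configuration is the
#' small desk-scale experiment (16 x 16 x 12 grid, 8 subjects per group,
#' exhaustive or 500-permutation inference) with the dissociation ground
#' truth; `paper_shape = TRUE` switches the grid to the full acquisition
#' matrix (70 x 70 x 32). A YAML file with any of the scalar fields
#' (`seed`, `grid_dims`, `n_permutations`, ...) can override the defaults.
#'
#' @param seed Global seed; every stage's randomness derives from it.
#' @param acquisition,design,truth,hrf,sphere,classifier,inference Stage
#'   specifications (see the respective constructors). `design` is a list
#'   of [make_block_design()] arguments.
#' @param smoothing_univariate,smoothing_mvpa [smoothing_spec()]s for the
#'   two tracks.
#' @param gm_shape Mask shape passed to [make_gm_mask()].
#' @param output_dir Directory for NIfTI / table outputs (NULL = in memory).
#' @param paper_shape Use the full 70 x 70 x 32 grid.
#' @param file Optional YAML file overriding scalar fields.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            acquisition = NULL,
                            design = list(n_per_condition = 20L,
                                          block_dur_s = 8, ibi_s = 2,
                                          lead_in_s = 10),
                            truth = dissociation_truth(),
                            hrf = hrf_spec(),
                            sphere = sphere_spec(),
                            smoothing_univariate = smoothing_spec(6, "zero_pad"),
                            smoothing_mvpa = smoothing_spec(6, "renormalize_in_mask"),
                            classifier = classifier_spec(),
                            inference = inference_spec(n_permutations = 500L),
                            gm_shape = "ellipsoid",
                            output_dir = NULL,
                            paper_shape = FALSE,
                            file = NULL) {
  if (!is.null(file)) {
    ov <- yaml::read_yaml(file)
    if (!is.null(ov$seed)) seed <- ov$seed
    if (!is.null(ov$grid_dims))
      acquisition <- acquisition_spec(grid_dims = ov$grid_dims)
    if (!is.null(ov$n_permutations))
      inference$n_permutations <- as.integer(ov$n_permutations)
    if (!is.null(ov$alpha_fwe)) inference$alpha_fwe <- ov$alpha_fwe
    if (!is.null(ov$fwhm_mm)) {
      smoothing_univariate$fwhm_mm <- ov$fwhm_mm
      smoothing_mvpa$fwhm_mm <- ov$fwhm_mm
    }
    if (!is.null(ov$radius_mm)) sphere$radius_mm <- ov$radius_mm
    if (!is.null(ov$output_dir)) output_dir <- ov$output_dir
    if (!is.null(ov$group_sizes))
      truth$group_sizes <- c(F = as.integer(ov$group_sizes[[1]]),
                             M = as.integer(ov$group_sizes[[2]]))
  }
  acquisition <- acquisition %||%
    acquisition_spec(grid_dims = if (paper_shape) c(70L, 70L, 32L)
                     else c(16L, 16L, 12L))
  cfg <- structure(list(seed = as.integer(seed), acquisition = acquisition,
                        design = design, truth = truth, hrf = hrf,
                        sphere = sphere,
                        smoothing_univariate = smoothing_univariate,
                        smoothing_mvpa = smoothing_mvpa,
                        classifier = classifier, inference = inference,
                        gm_shape = gm_shape, output_dir = output_dir),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg$acquisition, "acquisition_spec"),
            inherits(cfg$truth, "ground_truth_spec"),
            inherits(cfg$hrf, "hrf_spec"),
            inherits(cfg$sphere, "sphere_spec"),
            inherits(cfg$smoothing_univariate, "smoothing_spec"),
            inherits(cfg$smoothing_mvpa, "smoothing_spec"),
            inherits(cfg$classifier, "classifier_spec"),
            inherits(cfg$inference, "inference_spec"))
  invisible(cfg)
}

#' Run the full two-track experiment
#'
#' Executes, from the global seed alone: cohort simulation; the shared
#' 40-column per-block GLM per subject; (a) the univariate track -- the
#' vocal minus non-vocal contrast image, smoothed, one-sample group tests
#' per group and two-sample between-group tests; (b) the multivariate track
#' -- searchlight decoding, chance centring and smoothing, the same group
#' tests on accuracy maps. Between-group tests (both tracks, both
#' directions) are restricted to the conjunction mask of voxels decoding
#' above chance (uncorrected p < `mask_alpha_uncorrected`) in both groups.
#' Significant voxels are those with `p_fwe <= alpha_fwe`; cluster tables
#' report peaks, sizes and Cohen's d at the peak.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress (default TRUE).
#' @return An object of class `run_report`; see `print()` for a summary.
#'   Fields: `univariate` and `mvpa` (each with group results, between-group
#'   results and cluster tables), `conjunction` (mask and voxel count),
#'   `subject_maps`, `config`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  validate_pipeline_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  acq <- config$acquisition
  gm <- make_gm_mask(acq$grid_dims, acq$voxel_size_mm, config$gm_shape)
  design <- make_block_design(config$design$n_per_condition %||% 20L,
                              config$design$block_dur_s %||% 8,
                              config$design$ibi_s %||% 2,
                              acq,
                              config$design$lead_in_s %||% 10,
                              seed = derive_seed(config$seed, 1L))
  say("simulate: %d + %d subjects on %s grid",
      config$truth$group_sizes[["F"]], config$truth$group_sizes[["M"]],
      paste(acq$grid_dims, collapse = "x"))
  cohort <- simulate_cohort(design, config$truth, acq, gm,
                            seed = derive_seed(config$seed, 2L),
                            hrf = config$hrf)
  X <- build_design_matrix(design, acq, config$hrf)

  say("glm + searchlight: %d subjects", length(cohort$subjects))
  con_maps <- vector("list", length(cohort$subjects))
  acc_maps <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    betas <- fit_glm(s, X, gm)
    cm <- contrast_map(betas)
    cv <- cm$values
    cv[is.na(cv)] <- 0                       # outside the fitted mask
    con_maps[[i]] <- gaussian_smooth(cv, config$smoothing_univariate,
                                     acq$voxel_size_mm)
    acc <- searchlight_map(betas, gm, config$sphere, config$classifier)
    acc_maps[[i]] <- list(map = acc, smoothed = center_and_smooth(acc,
                                       config$smoothing_mvpa))
  }
  isF <- cohort$group_labels == "F"
  valid <- acc_maps[[1]]$map$valid_mask
  for (m in acc_maps) valid <- valid & m$map$valid_mask
  mvpa_maps <- lapply(acc_maps, function(m) {
    v <- m$smoothed
    v[is.na(v)] <- 0
    v
  })

  infer <- function(spec_tail, ...) {
    sp <- config$inference
    sp$tail <- spec_tail
    sp$seed <- sp$seed %||% derive_seed(config$seed, 3L)
    sp
  }
  say("group inference: one-sample per group, both tracks")
  uni_F <- one_sample_perm_test(con_maps[isF], gm, infer("greater"))
  uni_M <- one_sample_perm_test(con_maps[!isF], gm, infer("greater"))
  mvpa_F <- one_sample_perm_test(mvpa_maps[isF], valid, infer("greater"))
  mvpa_M <- one_sample_perm_test(mvpa_maps[!isF], valid, infer("greater"))

  conj <- conjunction_mask(mvpa_F, mvpa_M, config$inference$mask_alpha_uncorrected)
  say("conjunction mask: %d voxels", sum(conj))

  between <- list()
  if (sum(conj) > 0) {
    say("group inference: between groups inside the conjunction mask")
    between$uni_f_gt_m <- two_sample_perm_test(con_maps[isF], con_maps[!isF],
                                               conj, infer("greater"))
    between$uni_m_gt_f <- two_sample_perm_test(con_maps[!isF], con_maps[isF],
                                               conj, infer("greater"))
    between$mvpa_f_gt_m <- two_sample_perm_test(mvpa_maps[isF], mvpa_maps[!isF],
                                                conj, infer("greater"))
    between$mvpa_m_gt_f <- two_sample_perm_test(mvpa_maps[!isF], mvpa_maps[isF],
                                                conj, infer("greater"))
  }

  alpha <- config$inference$alpha_fwe
  cluster_report <- function(res, maps_hi, maps_lo) {
    if (is.null(res)) return(NULL)
    sig <- !is.na(res$p_fwe_map) & res$p_fwe_map <= alpha
    tab <- clusterize(res$t_map, sig, -Inf)
    if (nrow(tab) > 0) {
      tab$cohens_d <- vapply(seq_len(nrow(tab)), function(r) {
        a <- vapply(maps_hi, function(m) m[tab$peak_x[r], tab$peak_y[r],
                                           tab$peak_z[r]], numeric(1))
        b <- vapply(maps_lo, function(m) m[tab$peak_x[r], tab$peak_y[r],
                                           tab$peak_z[r]], numeric(1))
        tryCatch(cohens_d(a, b), error = function(e) NA_real_)
      }, numeric(1))
    } else tab$cohens_d <- numeric(0)
    tab
  }

  report <- structure(list(
    config = config,
    group_labels = cohort$group_labels,
    univariate = list(
      group = list(F = uni_F, M = uni_M),
      between = between[c("uni_f_gt_m", "uni_m_gt_f")],
      clusters_f_gt_m = cluster_report(between$uni_f_gt_m,
                                       con_maps[isF], con_maps[!isF]),
      clusters_m_gt_f = cluster_report(between$uni_m_gt_f,
                                       con_maps[!isF], con_maps[isF])),
    mvpa = list(
      group = list(F = mvpa_F, M = mvpa_M),
      between = between[c("mvpa_f_gt_m", "mvpa_m_gt_f")],
      clusters_f_gt_m = cluster_report(between$mvpa_f_gt_m,
                                       mvpa_maps[isF], mvpa_maps[!isF]),
      clusters_m_gt_f = cluster_report(between$mvpa_m_gt_f,
                                       mvpa_maps[!isF], mvpa_maps[isF])),
    conjunction = list(mask = conj, n_voxels = sum(conj)),
    subject_maps = list(contrast = con_maps, accuracy = acc_maps,
                        mvpa = mvpa_maps, valid_mask = valid),
    provenance = list(seed = config$seed, subject_seeds = cohort$seeds,
                      n_permutations = config$inference$n_permutations,
                      elapsed_s = as.numeric(Sys.time() - t0, units = "secs"),
                      r_version = R.version.string)),
    class = "run_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

n_sig_voxels <- function(res, alpha) {
  if (is.null(res)) return(0L)
  sum(res$p_fwe_map <= alpha, na.rm = TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  alpha <- x$config$inference$alpha_fwe
  cat("== voxlight run report ==\n")
  cat(sprintf("cohort: %d F + %d M, grid %s, seed %d\n",
              sum(x$group_labels == "F"), sum(x$group_labels == "M"),
              paste(x$config$acquisition$grid_dims, collapse = "x"),
              x$config$seed))
  cat(sprintf("conjunction mask (above-chance decoding in both groups): %d voxels\n",
              x$conjunction$n_voxels))
  cat(sprintf("FWE-significant voxels at alpha = %.2f:\n", alpha))
  cat(sprintf("  univariate F>M: %d | M>F: %d\n",
              n_sig_voxels(x$univariate$between$uni_f_gt_m, alpha),
              n_sig_voxels(x$univariate$between$uni_m_gt_f, alpha)))
  cat(sprintf("  MVPA       F>M: %d | M>F: %d\n",
              n_sig_voxels(x$mvpa$between$mvpa_f_gt_m, alpha),
              n_sig_voxels(x$mvpa$between$mvpa_m_gt_f, alpha)))
  tab <- x$mvpa$clusters_f_gt_m
  if (!is.null(tab) && nrow(tab) > 0) {
    cat("MVPA F>M clusters:\n")
    print(tab, digits = 3)
  }
  cat(sprintf("elapsed: %.1f s\n", x$provenance$elapsed_s))
  invisible(x)
}

# write volumes / tables of a finished run
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- report$config$acquisition$voxel_size_mm
  wv <- function(d, f) write_volume(d, vs, file.path(dir, f))
  conj <- report$conjunction$mask
  wv(conj, "conjunction_mask.nii.gz")
  for (track in c("univariate", "mvpa")) {
    tr <- report[[track]]
    for (g in c("F", "M"))
      wv(tr$group[[g]]$t_map, sprintf("%s_group_%s_t.nii.gz", track, g))
    for (nm in names(tr$between)) {
      if (is.null(tr$between[[nm]])) next
      wv(tr$between[[nm]]$t_map, sprintf("%s_t.nii.gz", nm))
      wv(tr$between[[nm]]$p_fwe_map, sprintf("%s_p_fwe.nii.gz", nm))
    }
    for (cl in c("clusters_f_gt_m", "clusters_m_gt_f"))
      if (!is.null(tr[[cl]]))
        write_cluster_table(tr[[cl]], file.path(dir, sprintf("%s_%s.tsv",
                                                             track, cl)))
  }
  summary <- list(
    seed = report$config$seed,
    conjunction_voxels = report$conjunction$n_voxels,
    n_sig = list(
      univariate_f_gt_m = n_sig_voxels(report$univariate$between$uni_f_gt_m,
                                       report$config$inference$alpha_fwe),
      univariate_m_gt_f = n_sig_voxels(report$univariate$between$uni_m_gt_f,
                                       report$config$inference$alpha_fwe),
      mvpa_f_gt_m = n_sig_voxels(report$mvpa$between$mvpa_f_gt_m,
                                 report$config$inference$alpha_fwe),
      mvpa_m_gt_f = n_sig_voxels(report$mvpa$between$mvpa_m_gt_f,
                                 report$config$inference$alpha_fwe)))
  writeLines(yaml::as.yaml(summary), file.path(dir, "summary.yaml"))
  invisible(dir)
}
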