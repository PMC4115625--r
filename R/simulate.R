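#' Simulate one subject's block-design BOLD run
#'
#' The series is `baseline + drift + HRF-convolved block signal + noise`.
#' Each voxel of a planted region responds to block `b` with amplitude
#' `a(condition_b, group) + pattern_scale(group) * pat(v) * code(condition_b)`
#' (`code`: vocal +1, non-vocal -1); the signed pattern `pat` is seeded by
#' the ground truth's `pattern_seed` (identical across subjects in
#' `"shared"` mode, independently drawn per subject in `"subject"` mode)
#' and has exactly zero spatial mean over the region. The temporal profile
#' of each block is the same regressor later used by [build_design_matrix()],
#' so on noiseless data the GLM recovers the planted amplitudes exactly.
#' Gaussian noise (SD `noise_sd`, optional AR(1) with stationary variance
#' preserved) is added at every voxel. Identical `(inputs, seed)` give
#' bit-identical data.
#'
#' @param design A [block_design()].
#' @param truth A [ground_truth_spec()].
#' @param group_label `"F"` or `"M"`.
#' @param acquisition An [acquisition_spec()].
#' @param gm_mask Logical 3D gray-matter mask (default: ellipsoid).
#' @param seed Integer seed for this subject's noise and drift.
#' @param hrf An [hrf_spec()] used for the block temporal profile.
#' @return An object of class `subject_series` with fields `data`
#'   (4D array, grid x time), `acquisition`, `gm_mask`, `group_label`, `seed`.
#' @examples
#' acq <- acquisition_spec(grid_dims = c(8, 8, 6), n_volumes = 60)
#' d <- make_block_design(2, acquisition = acq, seed = 1)
#' s <- simulate_subject(d, ground_truth_spec(), "F", acq, seed = 7)
#' dim(s$data)
#' @export
simulate_subject <- function(design, truth, group_label, acquisition,
                             gm_mask = NULL, seed = 1L, hrf = hrf_spec()) {
  stopifnot(inherits(design, "block_design"),
            inherits(truth, "ground_truth_spec"),
            inherits(acquisition, "acquisition_spec"))
  if (!group_label %in% c("F", "M")) stop_("`group_label` must be 'F' or 'M'")
  dims <- acquisition$grid_dims
  nv <- acquisition$n_volumes
  gm_mask <- gm_mask %||% make_gm_mask(dims, acquisition$voxel_size_mm)
  if (!identical(dim(gm_mask), dims)) stop_("gm_mask grid mismatch")

  nb <- n_blocks(design)
  # temporal profile of every block (no drift/intercept here)
  Xb <- if (nb > 0L)
    build_design_matrix(design, acquisition, hrf,
                        n_cosine_drift = 0L, include_intercept = FALSE)$values
  else matrix(0, nv, 0)

  n_vox <- prod(dims)
  dat <- matrix(truth$baseline, nrow = nv, ncol = n_vox)

  # planted signal: per-region per-voxel block amplitudes
  if (nb > 0L && length(truth$regions) > 0L) {
    code <- ifelse(design$condition_labels == "vocal", 1, -1)
    amp_cond <- truth$univariate_amplitude[[group_label]][design$condition_labels]
    ps <- truth$pattern_scale[[group_label]]
    for (ri in seq_along(truth$regions)) {
      vox <- region_voxels(truth$regions[[ri]], dims, acquisition$voxel_size_mm)
      pat_seed <- if ((truth$pattern_mode %||% "shared") == "shared")
        truth$pattern_seed + ri
      else derive_seed(truth$pattern_seed + seed, ri)
      pat <- region_pattern(nrow(vox), pat_seed)
      # amplitude matrix: n_blocks x n_region_voxels
      amp <- outer(amp_cond, rep(1, nrow(vox))) + ps * outer(code, pat)
      lin <- vox_linear(vox, dims)
      dat[, lin] <- dat[, lin] + Xb %*% amp
    }
  }

  set.seed(seed)
  if (truth$drift_amplitude > 0 && truth$n_drift > 0L) {
    k <- seq_len(truth$n_drift)
    basis <- sapply(k, function(kk) cos(pi * kk * (seq_len(nv) - 0.5) / nv))
    coefs <- matrix(rnorm(truth$n_drift * n_vox, sd = truth$drift_amplitude),
                    truth$n_drift, n_vox)
    dat <- dat + basis %*% coefs
  }
  if (truth$noise_sd > 0) {
    eps <- matrix(rnorm(nv * n_vox, sd = truth$noise_sd), nv, n_vox)
    if (truth$ar1 != 0) {
      eps <- eps * sqrt(1 - truth$ar1^2)
      eps <- apply(eps, 2, function(e)
        as.numeric(stats::filter(e, truth$ar1, method = "recursive")))
    }
    dat <- dat + eps
  }

  structure(list(data = array(t(dat), dim = c(dims, nv)),
                 acquisition = acquisition, gm_mask = gm_mask,
                 group_label = group_label, seed = as.integer(seed)),
            class = "subject_series")
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("<subject_series> group %s, grid %s, %d volumes, seed %d\n",
              x$group_label, paste(dim(x$data)[1:3], collapse = "x"),
              dim(x$data)[4], x$seed))
  invisible(x)
}

#' Simulate a two-group cohort
#'
#' Simulates `group_sizes["F"]` female and `group_sizes["M"]` male subjects
#' with per-subject seeds derived deterministically from `seed`. All
#' subjects share the design, grid and gray-matter mask (the synthetic
#' cohort is generated already aligned in one common space).
#'
#' @inheritParams simulate_subject
#' @param seed Global seed from which per-subject seeds are derived.
#' @return List with elements `subjects` (list of `subject_series`),
#'   `group_labels`, `seeds`, `design`, `truth`, `acquisition`, `gm_mask`.
#' @export
simulate_cohort <- function(design, truth, acquisition, gm_mask = NULL,
                            seed = 1L, hrf = hrf_spec()) {
  gm_mask <- gm_mask %||%
    make_gm_mask(acquisition$grid_dims, acquisition$voxel_size_mm)
  labels <- c(rep("F", truth$group_sizes[["F"]]),
              rep("M", truth$group_sizes[["M"]]))
  seeds <- vapply(seq_along(labels), function(i) derive_seed(seed, i), 1L)
  subjects <- lapply(seq_along(labels), function(i)
    simulate_subject(design, truth, labels[i], acquisition, gm_mask,
                     seed = seeds[i], hrf = hrf))
  list(subjects = subjects, group_labels = labels, seeds = seeds,
       design = design, truth = truth, acquisition = acquisition,
       gm_mask = gm_mask)
}
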