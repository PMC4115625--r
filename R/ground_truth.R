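#' Planted region
#'
#' A spherical signal region given by its centre voxel (1-based index) and
#' radius in millimetres. Membership is by physical distance between voxel
#' centres; the region must lie entirely inside the grid.
#'
#' @param center Integer vector of 3 voxel indices.
#' @param radius_mm Radius in mm (>= 0).
#' @export
region <- function(center, radius_mm) {
  if (length(center) != 3L || any(!is.finite(center)))
    stop_("`center` must be 3 voxel indices")
  radius_mm <- check_scalar_num(radius_mm, "radius_mm", 0)
  list(center = as.integer(center), radius_mm = radius_mm)
}

#' Ground truth for the synthetic cohort
#'
#' Defines what is planted into simulated subjects. Each region's voxels
#' carry, per block, an amplitude
#' `a(condition, group) + pattern_scale(group) * pat(v) * code(condition)`
#' where `code(vocal) = +1`, `code(non-vocal) = -1` and `pat` is a fixed,
#' seeded, zero-mean signed pattern (balanced +1/-1, one 0 filler when the
#' region has an odd voxel count) shared by every subject. The pattern term
#' averages to zero over the region, so it adds multivoxel decodable
#' structure without any univariate contrast in expectation: mean amplitude
#' and pattern reliability are controlled independently, per group.
#'
#' @param regions List of [region()] objects.
#' @param baseline Baseline signal level.
#' @param univariate_amplitude Named list with one numeric vector per group
#'   (`F`, `M`), each named by condition (`vocal`, `non-vocal`): the mean
#'   per-block response amplitude, in signal units.
#' @param pattern_scale Named numeric (`F`, `M`): amplitude of the signed
#'   pattern, in signal units.
#' @param noise_sd White (optionally AR(1)) Gaussian noise SD, everywhere.
#' @param drift_amplitude SD of the coefficients of the low-order cosine
#'   drift added per voxel (0 disables drift).
#' @param n_drift Number of cosine drift components when drift is on.
#' @param ar1 Lag-1 autocorrelation of the temporal noise (default 0, white).
#' @param group_sizes Named integer (`F`, `M`): cohort group sizes.
#' @param pattern_seed Seed fixing the region patterns (shared mode) or the
#'   per-subject pattern derivation (subject mode).
#' @param pattern_mode `"shared"` (one pattern for every subject) or
#'   `"subject"` (an independent pattern per subject). A shared pattern is
#'   a fixed voxelwise effect: it survives averaging across subjects and is
#'   therefore visible to voxelwise univariate group contrasts. Subject-
#'   specific patterns leave within-subject decodability untouched while
#'   averaging out of the univariate contrast across subjects -- the regime
#'   in which group differences appear only in the multivariate track.
#' @return An object of class `ground_truth_spec`.
#' @examples
#' ground_truth_spec(regions = list(region(c(8, 8, 6), 6)),
#'                   pattern_scale = c(F = 1, M = 0))
#' @export
ground_truth_spec <- function(regions = list(),
                              baseline = 100,
                              univariate_amplitude = list(
                                F = c(vocal = 1, "non-vocal" = 0),
                                M = c(vocal = 1, "non-vocal" = 0)),
                              pattern_scale = c(F = 0, M = 0),
                              noise_sd = 1,
                              drift_amplitude = 0,
                              n_drift = 3L,
                              ar1 = 0,
                              group_sizes = c(F = 8L, M = 8L),
                              pattern_seed = 1234L,
                              pattern_mode = c("shared", "subject")) {
  pattern_mode <- match.arg(pattern_mode)
  for (r in regions)
    if (!is.list(r) || is.null(r$center) || is.null(r$radius_mm))
      stop_("each region must be built with region()")
  noise_sd <- check_scalar_num(noise_sd, "noise_sd", 0)
  drift_amplitude <- check_scalar_num(drift_amplitude, "drift_amplitude", 0)
  ar1 <- check_scalar_num(ar1, "ar1")
  if (abs(ar1) >= 1) stop_("`ar1` must lie in (-1, 1)")
  for (g in c("F", "M")) {
    a <- univariate_amplitude[[g]]
    if (is.null(a) || !all(c("vocal", "non-vocal") %in% names(a)))
      stop_("`univariate_amplitude$%s` needs named entries 'vocal', 'non-vocal'", g)
    if (is.na(pattern_scale[[g]]))
      stop_("`pattern_scale` needs entries for groups F and M")
    if (is.na(group_sizes[[g]]) || group_sizes[[g]] < 1)
      stop_("`group_sizes` needs positive entries for groups F and M")
  }
  structure(list(regions = regions, baseline = as.numeric(baseline),
                 univariate_amplitude = univariate_amplitude,
                 pattern_scale = pattern_scale, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 n_drift = as.integer(n_drift), ar1 = ar1,
                 group_sizes = group_sizes,
                 pattern_seed = as.integer(pattern_seed),
                 pattern_mode = pattern_mode),
            class = "ground_truth_spec")
}

# Voxels of one region: n x 3 index matrix. Errors when the region does not
# lie entirely inside the grid.
region_voxels <- function(reg, grid_dims, voxel_size_mm) {
  ctr <- reg$center
  if (!all(ctr >= 1L) || !any(in_grid(matrix(ctr, 1), grid_dims)))
    stop_("region centre (%s) lies outside the grid",
          paste(ctr, collapse = ", "))
  rmax <- floor(reg$radius_mm / voxel_size_mm)
  grid <- as.matrix(expand.grid(i = ctr[1] + (-rmax[1]:rmax[1]),
                                j = ctr[2] + (-rmax[2]:rmax[2]),
                                k = ctr[3] + (-rmax[3]:rmax[3])))
  d2 <- ((grid[, 1] - ctr[1]) * voxel_size_mm[1])^2 +
        ((grid[, 2] - ctr[2]) * voxel_size_mm[2])^2 +
        ((grid[, 3] - ctr[3]) * voxel_size_mm[3])^2
  vox <- grid[d2 <= reg$radius_mm^2 + 1e-9, , drop = FALSE]
  if (!all(in_grid(vox, grid_dims)))
    stop_("region at (%s), radius %g mm extends outside the grid",
          paste(ctr, collapse = ", "), reg$radius_mm)
  unname(vox)
}

# Fixed signed pattern over n voxels: balanced +1/-1 in a seeded random
# order; one 0 filler when n is odd. Exactly zero mean by construction.
region_pattern <- function(n, seed) {
  half <- n %/% 2L
  vals <- c(rep(1, half), rep(-1, half), if (n %% 2L == 1L) 0)
  with_seed(seed, sample(vals))
}
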