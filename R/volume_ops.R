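#' Searchlight sphere specification
#'
#' @param radius_mm Sphere radius in millimetres (default 6).
#' @param min_gm_fraction Minimum fraction of the sphere's in-grid voxels
#'   that must be gray matter for the sphere to enter the analysis
#'   (default 0.5, compared with `>=`).
#' @return An object of class `sphere_spec`.
#' @export
sphere_spec <- function(radius_mm = 6, min_gm_fraction = 0.5) {
  radius_mm <- check_scalar_num(radius_mm, "radius_mm", 0)
  min_gm_fraction <- check_scalar_num(min_gm_fraction, "min_gm_fraction", 0)
  if (min_gm_fraction > 1) stop_("`min_gm_fraction` must lie in [0, 1]")
  structure(list(radius_mm = radius_mm, min_gm_fraction = min_gm_fraction),
            class = "sphere_spec")
}

#' Integer voxel offsets of a searchlight sphere
#'
#' All integer offsets `(i, j, k)` whose physical centre distance
#' `sqrt((i dx)^2 + (j dy)^2 + (k dz)^2)` is at most `radius_mm` (closed
#' ball on voxel centres). Always contains `(0, 0, 0)` and is symmetric
#' under negation. With 6 mm radius the set holds 33 offsets at isotropic
#' 3 mm spacing and 31 at 3 x 3 x 3.3 mm.
#'
#' @param radius_mm Radius in mm (>= 0).
#' @param voxel_size_mm 3 positive spacings in mm.
#' @return Integer matrix with 3 columns, one offset per row.
#' @examples
#' nrow(sphere_offsets(6, c(3, 3, 3)))    # 33
#' nrow(sphere_offsets(6, c(3, 3, 3.3)))  # 31
#' @export
sphere_offsets <- function(radius_mm, voxel_size_mm) {
  radius_mm <- check_scalar_num(radius_mm, "radius_mm", 0)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop_("`voxel_size_mm` must be 3 positive spacings")
  rmax <- floor(radius_mm / voxel_size_mm)
  g <- as.matrix(expand.grid(i = -rmax[1]:rmax[1], j = -rmax[2]:rmax[2],
                             k = -rmax[3]:rmax[3]))
  d2 <- (g[, 1] * voxel_size_mm[1])^2 + (g[, 2] * voxel_size_mm[2])^2 +
        (g[, 3] * voxel_size_mm[3])^2
  out <- g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  storage.mode(out) <- "integer"
  unname(out)
}

#' Extract one searchlight sphere
#'
#' Drops offsets falling outside the grid, then applies the gray-matter
#' criterion: the sphere is valid when the fraction of its in-grid voxels
#' inside `gm_mask` is at least `min_gm_fraction`. Only the in-gray-matter
#' voxels are returned as members.
#'
#' @param center Integer vector of 3 voxel indices (1-based), inside the grid.
#' @param offsets Offset matrix from [sphere_offsets()].
#' @param gm_mask Logical 3D mask.
#' @param min_gm_fraction Validity threshold (compared with `>=`).
#' @return List with `indices` (n x 3 integer matrix of in-gray-matter voxel
#'   indices) and `valid` (logical).
#' @export
extract_sphere <- function(center, offsets, gm_mask, min_gm_fraction = 0.5) {
  dims <- dim(gm_mask)
  center <- as.integer(center)
  if (!in_grid(matrix(center, 1), dims))
    stop_("sphere centre (%s) lies outside the grid",
          paste(center, collapse = ", "))
  vox <- sweep(offsets, 2L, center, `+`)
  vox <- vox[in_grid(vox, dims), , drop = FALSE]
  gm <- gm_mask[vox_linear(vox, dims)]
  frac <- if (nrow(vox) > 0L) sum(gm) / nrow(vox) else 0
  list(indices = vox[gm, , drop = FALSE], valid = frac >= min_gm_fraction)
}

#' Smoothing specification
#'
#' Isotropic Gaussian smoothing in millimetre units: per-axis
#' `sigma_mm = fwhm_mm / (2 sqrt(2 ln 2))`, converted to voxel units by each
#' axis's spacing. `zero_pad` treats values outside the volume as 0;
#' `renormalize_in_mask` divides the smoothed masked volume by the smoothed
#' mask, undoing boundary attenuation so a mask-constant volume is preserved.
#'
#' @param fwhm_mm Full width at half maximum, mm (>= 0; 0 = identity).
#' @param boundary_rule `"zero_pad"` or `"renormalize_in_mask"`.
#' @return An object of class `smoothing_spec`.
#' @export
smoothing_spec <- function(fwhm_mm = 6,
                           boundary_rule = c("zero_pad", "renormalize_in_mask")) {
  fwhm_mm <- check_scalar_num(fwhm_mm, "fwhm_mm", 0)
  structure(list(fwhm_mm = fwhm_mm, boundary_rule = match.arg(boundary_rule)),
            class = "smoothing_spec")
}

fwhm_to_sigma <- function(fwhm_mm) fwhm_mm / (2 * sqrt(2 * log(2)))

# 1D zero-padded convolution of a 3D array along `axis` with kernel `k`
# (odd length, centre at (length+1)/2).
conv_axis <- function(arr, k, axis) {
  r <- (length(k) - 1L) / 2L
  dims <- dim(arr)
  out <- array(0, dims)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    if (k[j] == 0) next
    # out[i] += k[j] * arr[i + off] along `axis`, zero pad
    n <- dims[axis]
    src_lo <- max(1L, 1L + off); src_hi <- min(n, n + off)
    if (src_lo > src_hi) next
    dst_lo <- src_lo - off; dst_hi <- src_hi - off
    idx_dst <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    idx_src <- idx_dst
    idx_dst[[axis]] <- dst_lo:dst_hi
    idx_src[[axis]] <- src_lo:src_hi
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      k[j] * arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}

gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian filtering with per-axis sigma in voxels equal to
#' `sigma_mm / spacing`. `fwhm_mm = 0` returns the input unchanged. Under
#' `renormalize_in_mask` the result is `smooth(volume * mask) /
#' smooth(mask)`, defined on the mask (NA outside).
#'
#' @param volume 3D numeric array.
#' @param spec A [smoothing_spec()].
#' @param voxel_size_mm 3 positive spacings in mm.
#' @param mask Logical 3D mask (`renormalize_in_mask` only; default all TRUE).
#' @return 3D numeric array.
#' @export
gaussian_smooth <- function(volume, spec = smoothing_spec(), voxel_size_mm,
                            mask = NULL) {
  stopifnot(inherits(spec, "smoothing_spec"))
  if (length(dim(volume)) != 3L) stop_("`volume` must be a 3D array")
  if (spec$fwhm_mm == 0) {
    if (spec$boundary_rule == "renormalize_in_mask" && !is.null(mask)) {
      volume[!mask] <- NA_real_
    }
    return(volume)
  }
  sig_vox <- fwhm_to_sigma(spec$fwhm_mm) / voxel_size_mm
  kerns <- lapply(sig_vox, gauss_kernel_1d)
  smooth3 <- function(a) {
    for (ax in 1:3) if (length(kerns[[ax]]) > 1L) a <- conv_axis(a, kerns[[ax]], ax)
    a
  }
  if (spec$boundary_rule == "zero_pad") {
    return(smooth3(volume))
  }
  mask <- mask %||% array(TRUE, dim(volume))
  v <- volume
  v[!mask] <- 0
  num <- smooth3(v)
  den <- smooth3(array(as.numeric(mask), dim(mask)))
  out <- array(NA_real_, dim(volume))
  ok <- mask & den > 1e-12
  out[ok] <- num[ok] / den[ok]
  out
}
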