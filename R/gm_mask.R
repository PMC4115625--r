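#' Build a gray-matter mask
#'
#' Three modes: `"full"` (all voxels), `"ellipsoid"` (voxel centres inside an
#' ellipsoid, by default centred on the grid with semi-axes spanning half the
#' physical grid extent -- a crude brain-shaped mask for synthetic data), and
#' `"probability_map"` (threshold a tissue-probability volume at
#' `threshold`, strictly greater, emulating a binary gray-matter template at
#' probability level 0.5).
#'
#' Voxel centres are at `(i - 0.5) * spacing` along each axis.
#'
#' @param grid_dims 3 positive integers.
#' @param voxel_size_mm 3 positive spacings in mm.
#' @param shape `"ellipsoid"`, `"full"` or `"probability_map"`.
#' @param probability_map 3D array of probabilities in `[0, 1]`
#'   (`probability_map` mode only).
#' @param threshold Probability threshold; a voxel is gray matter when its
#'   probability is strictly greater.
#' @param semi_axes_mm,center_mm Optional ellipsoid geometry overrides (mm).
#' @return Logical 3D array of dimension `grid_dims`.
#' @examples
#' m <- make_gm_mask(c(16, 16, 12), c(3, 3, 3.3))
#' sum(m)
#' @export
make_gm_mask <- function(grid_dims, voxel_size_mm,
                         shape = c("ellipsoid", "full", "probability_map"),
                         probability_map = NULL, threshold = 0.5,
                         semi_axes_mm = NULL, center_mm = NULL) {
  shape <- match.arg(shape)
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 1))
    stop_("`grid_dims` must be 3 positive integers")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop_("`voxel_size_mm` must be 3 positive spacings")

  if (shape == "full")
    return(array(TRUE, dim = grid_dims))

  if (shape == "probability_map") {
    if (is.null(probability_map))
      stop_("`probability_map` is required for shape = 'probability_map'")
    if (!identical(dim(probability_map), as.integer(grid_dims)))
      stop_("`probability_map` dimensions do not match `grid_dims`")
    if (any(!is.finite(probability_map)) ||
        any(probability_map < 0) || any(probability_map > 1))
      stop_("probability map values must lie in [0, 1]")
    return(array(probability_map > threshold, dim = grid_dims))
  }

  extent <- grid_dims * voxel_size_mm
  semi <- semi_axes_mm %||% (extent / 2)
  ctr <- center_mm %||% (extent / 2)
  cx <- ((seq_len(grid_dims[1]) - 0.5) * voxel_size_mm[1] - ctr[1]) / semi[1]
  cy <- ((seq_len(grid_dims[2]) - 0.5) * voxel_size_mm[2] - ctr[2]) / semi[2]
  cz <- ((seq_len(grid_dims[3]) - 0.5) * voxel_size_mm[3] - ctr[3]) / semi[3]
  d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  array(d2 <= 1, dim = grid_dims)
}
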