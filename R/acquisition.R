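#' Acquisition geometry and timing
#'
#' Describes one functional run: repetition time, number of volumes, the
#' voxel grid and the voxel size. Defaults follow a standard 3 T voice
#' localizer protocol: TR 2 s, 310 volumes (620 s run), 3 x 3 x 3 mm voxels
#' acquired with a 0.3 mm inter-slice gap, so the effective slice spacing is
#' 3.3 mm, on a 70 x 70 x 32 grid.
#'
#' @param tr_s Repetition time in seconds (> 0).
#' @param n_volumes Number of volumes in the run (>= 1).
#' @param grid_dims Integer vector of 3 positive grid dimensions.
#' @param voxel_size_mm Numeric vector of 3 positive voxel spacings in mm;
#'   the third entry is slice thickness plus inter-slice gap.
#' @return An object of class `acquisition_spec`.
#' @examples
#' acquisition_spec()
#' acquisition_spec(grid_dims = c(16, 16, 12))
#' @export
acquisition_spec <- function(tr_s = 2, n_volumes = 310L,
                             grid_dims = c(70L, 70L, 32L),
                             voxel_size_mm = c(3, 3, 3.3)) {
  tr_s <- check_scalar_num(tr_s, "tr_s", 0, strict = TRUE)
  if (length(n_volumes) != 1L || !is.finite(n_volumes) || n_volumes < 1)
    stop_("`n_volumes` must be a single integer >= 1")
  n_volumes <- as.integer(n_volumes)
  if (length(grid_dims) != 3L || any(!is.finite(grid_dims)) || any(grid_dims < 1))
    stop_("`grid_dims` must be 3 positive integers")
  grid_dims <- as.integer(grid_dims)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop_("`voxel_size_mm` must be 3 positive spacings in mm")
  structure(list(tr_s = tr_s, n_volumes = n_volumes, grid_dims = grid_dims,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("<acquisition_spec> TR %gs, %d volumes (%gs), grid %s, voxel %s mm\n",
              x$tr_s, x$n_volumes, x$tr_s * x$n_volumes,
              paste(x$grid_dims, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}

run_duration_s <- function(acquisition) acquisition$tr_s * acquisition$n_volumes
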