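#' Fit the voxelwise GLM
#'
#' Ordinary least squares per voxel inside the analysis mask:
#' `beta = (X'X)^-1 X'y`, residual variance `RSS / dof` with
#' `dof = n_volumes - n_regressors`. The per-block coefficients are the
#' classification exemplars used by the searchlight; voxels outside the
#' mask are invalid (NA).
#'
#' @param series A [simulate_subject()] result (or any `subject_series`).
#' @param X A [build_design_matrix()] result; must have full column rank and
#'   fewer regressors than volumes.
#' @param mask Logical 3D analysis mask; defaults to the subject's
#'   gray-matter mask.
#' @return An object of class `beta_maps`: `betas` (4D, grid x n_blocks),
#'   `condition_labels`, `residual_variance` (3D), `dof`, `mask`,
#'   `voxel_size_mm`.
#' @export
fit_glm <- function(series, X, mask = NULL) {
  stopifnot(inherits(series, "subject_series"), inherits(X, "design_matrix"))
  dims <- dim(series$data)[1:3]
  nv <- dim(series$data)[4]
  mask <- mask %||% series$gm_mask
  if (!identical(dim(mask), as.integer(dims)) &&
      !identical(dim(mask), dims)) stop_("mask grid mismatch")
  Xm <- X$values
  if (nrow(Xm) != nv) stop_("design matrix has %d rows but the series %d volumes",
                            nrow(Xm), nv)
  p <- ncol(Xm)
  if (p >= nv) stop_("%d regressors for %d volumes leaves no residual degrees of freedom",
                     p, nv)
  qr_x <- qr(Xm)
  if (qr_x$rank < p) stop_("design matrix is rank deficient")

  idx <- which(mask)
  if (length(idx) == 0L) stop_("empty analysis mask")
  Y <- matrix(series$data, prod(dims), nv)[idx, , drop = FALSE]
  Y <- t(Y)                                   # n_volumes x n_mask_voxels
  coefs <- qr.coef(qr_x, Y)                   # p x V
  resid <- Y - Xm %*% coefs
  dof <- nv - p
  rv <- colSums(resid^2) / dof

  nb <- length(X$block_cols)
  betas <- array(NA_real_, dim = c(dims, nb))
  bm <- matrix(betas, prod(dims), nb)
  bm[idx, ] <- t(coefs[X$block_cols, , drop = FALSE])
  betas <- array(bm, dim = c(dims, nb))
  residual_variance <- array(NA_real_, dim = dims)
  residual_variance[idx] <- rv

  structure(list(betas = betas, condition_labels = X$block_condition,
                 residual_variance = residual_variance, dof = dof,
                 mask = array(as.logical(mask), dim = dims),
                 voxel_size_mm = series$acquisition$voxel_size_mm),
            class = "beta_maps")
}

#' @export
print.beta_maps <- function(x, ...) {
  cat(sprintf("<beta_maps> %d block betas on grid %s, dof %d\n",
              dim(x$betas)[4], paste(dim(x$betas)[1:3], collapse = "x"), x$dof))
  invisible(x)
}

#' Subject-level contrast image
#'
#' Computes the voxelwise weighted combination `c'beta` of the per-block
#' coefficients. The default weights are `+1/n_vocal` on vocal blocks and
#' `-1/n_nonvocal` on non-vocal blocks, i.e. the mean vocal minus non-vocal
#' response.
#'
#' @param betas A [fit_glm()] result.
#' @param weights Numeric vector, one weight per block regressor; difference
#'   contrasts should sum to 0.
#' @return An object of class `contrast_map`: `values` (3D), the
#'   `contrast_vector`, `mask` and `voxel_size_mm`.
#' @export
contrast_map <- function(betas, weights = NULL) {
  stopifnot(inherits(betas, "beta_maps"))
  nb <- dim(betas$betas)[4]
  if (is.null(weights)) {
    vocal <- betas$condition_labels == "vocal"
    weights <- ifelse(vocal, 1 / sum(vocal), -1 / sum(!vocal))
  }
  if (length(weights) != nb)
    stop_("%d weights supplied for %d block regressors", length(weights), nb)
  dims <- dim(betas$betas)[1:3]
  vals <- matrix(betas$betas, prod(dims), nb) %*% weights
  structure(list(values = array(vals, dim = dims),
                 contrast_vector = as.numeric(weights),
                 mask = betas$mask, voxel_size_mm = betas$voxel_size_mm),
            class = "contrast_map")
}
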