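#' Linear classifier specification
#'
#' A linear maximum-margin (hinge-loss) support vector machine, trained in
#' the dual by deterministic coordinate descent. No feature scaling is
#' applied (beta exemplars are commensurate across voxels). A decision value
#' of exactly 0 predicts the positive class (the second condition label in
#' sorted order, i.e. `vocal` for the vocal / non-vocal contrast).
#'
#' @param regularization_c Soft-margin cost C (> 0, default 1).
#' @param fit_intercept Fit an intercept (as an augmented, regularised
#'   constant feature; default TRUE).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(regularization_c = 1, fit_intercept = TRUE) {
  regularization_c <- check_scalar_num(regularization_c, "regularization_c",
                                       0, strict = TRUE)
  structure(list(kind = "linear_svm", regularization_c = regularization_c,
                 fit_intercept = isTRUE(fit_intercept)),
            class = "classifier_spec")
}

label_to_pm1 <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2L)
    stop_("exactly two classes are required, got %d", nlevels(f))
  ifelse(f == levels(f)[2L], 1L, -1L)  # second sorted level is positive
}

#' Leave-one-out cross-validated classification accuracy
#'
#' For each exemplar, the classifier is trained on the remaining `n - 1`
#' and predicts the held-out one; the accuracy is the fraction of correct
#' predictions. Deterministic given `(X, y, clf)`.
#'
#' @param X Numeric matrix, exemplars in rows, features in columns.
#' @param y Vector of two class labels (factor, character or numeric).
#' @param clf A [classifier_spec()].
#' @return Accuracy in `[0, 1]` (a multiple of `1 / nrow(X)`).
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(40, 5), 10), matrix(rnorm(40, -5), 10))
#' loo_cv_accuracy(X, rep(c("a", "b"), each = 10))
#' @export
loo_cv_accuracy <- function(X, y, clf = classifier_spec()) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_("at least 2 exemplars are required")
  if (length(y) != nrow(X)) stop_("one label per exemplar is required")
  if (any(!is.finite(X))) stop_("features must be finite (no NA/NaN/Inf)")
  ypm <- label_to_pm1(y)
  cpp_loo_accuracy(X, as.integer(ypm), clf$regularization_c,
                   clf$fit_intercept, 1e-3, 1000L)
}

# per-voxel counts of in-grid and in-gray-matter sphere members, via
# zero-padded shift sums over the offset set
offset_counts <- function(gm_mask, offsets) {
  dims <- dim(gm_mask)
  gmn <- array(as.numeric(gm_mask), dims)
  n_gm <- array(0, dims); n_grid <- array(0, dims)
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    src <- dst <- vector("list", 3L)
    ok <- TRUE
    for (ax in 1:3) {
      lo <- max(1L, 1L + off[ax]); hi <- min(dims[ax], dims[ax] + off[ax])
      if (lo > hi) { ok <- FALSE; break }
      src[[ax]] <- lo:hi
      dst[[ax]] <- (lo - off[ax]):(hi - off[ax])
    }
    if (!ok) next
    n_grid[dst[[1]], dst[[2]], dst[[3]]] <-
      n_grid[dst[[1]], dst[[2]], dst[[3]]] + 1
    n_gm[dst[[1]], dst[[2]], dst[[3]]] <-
      n_gm[dst[[1]], dst[[2]], dst[[3]]] + gmn[src[[1]], src[[2]], src[[3]]]
  }
  list(gm = n_gm, grid = n_grid)
}

#' Whole-brain searchlight decoding map
#'
#' For each voxel whose sphere passes the gray-matter criterion, the
#' sphere's beta exemplars (`n_blocks` rows, one column per member voxel)
#' are classified under leave-one-out cross-validation and the accuracy is
#' stored at the central voxel. Features are restricted to the sphere's
#' in-gray-matter voxels by default (`feature_space = "gray_matter"`);
#' `"in_grid"` instead uses every in-grid sphere voxel with available betas.
#'
#' @param betas A [fit_glm()] result.
#' @param gm_mask Logical 3D mask; defaults to the mask stored in `betas`.
#' @param sphere A [sphere_spec()].
#' @param clf A [classifier_spec()].
#' @param feature_space `"gray_matter"` or `"in_grid"`.
#' @return An object of class `accuracy_map`: `values` (3D, NA where
#'   invalid), `valid_mask`, `chance_level` (1 / n_classes), `sphere_spec`,
#'   `voxel_size_mm`.
#' @export
searchlight_map <- function(betas, gm_mask = NULL, sphere = sphere_spec(),
                            clf = classifier_spec(),
                            feature_space = c("gray_matter", "in_grid")) {
  stopifnot(inherits(betas, "beta_maps"), inherits(sphere, "sphere_spec"))
  feature_space <- match.arg(feature_space)
  gm_mask <- gm_mask %||% betas$mask
  dims <- dim(betas$betas)[1:3]
  if (!identical(dim(gm_mask), as.integer(dims)) &&
      !identical(dim(gm_mask), dims)) stop_("gm_mask grid mismatch")
  labs <- betas$condition_labels
  if (min(table(labs)) < 2L) stop_("need at least 2 blocks per condition")
  nb <- length(labs)

  offsets <- sphere_offsets(sphere$radius_mm, betas$voxel_size_mm)
  counts <- offset_counts(gm_mask, offsets)
  valid <- counts$gm / pmax(counts$grid, 1) >= sphere$min_gm_fraction

  # feature voxels: finite betas, and gray matter under the default rule
  finite_ok <- is.finite(betas$betas[, , , 1L])
  feat_ok <- if (feature_space == "gray_matter") (gm_mask & finite_ok) else finite_ok
  feat_idx <- which(feat_ok)
  if (length(feat_idx) == 0L) stop_("no feature voxels available")
  col_of <- array(0L, dims)
  col_of[feat_idx] <- seq_along(feat_idx)
  B <- t(matrix(betas$betas, prod(dims), nb)[feat_idx, , drop = FALSE])

  centers <- which(valid, arr.ind = TRUE)
  if (nrow(centers) == 0L) stop_("no valid searchlight sphere anywhere")
  spheres <- vector("list", nrow(centers))
  keep <- logical(nrow(centers))
  for (ci in seq_len(nrow(centers))) {
    vox <- sweep(offsets, 2L, centers[ci, ], `+`)
    vox <- vox[in_grid(vox, dims), , drop = FALSE]
    cols <- col_of[vox_linear(vox, dims)]
    cols <- cols[cols > 0L]
    if (length(cols) > 0L) { spheres[[ci]] <- cols; keep[ci] <- TRUE }
  }
  valid[vox_linear(centers[!keep, , drop = FALSE], dims)] <- FALSE
  centers <- centers[keep, , drop = FALSE]
  spheres <- spheres[keep]
  if (nrow(centers) == 0L) stop_("no valid searchlight sphere anywhere")

  ypm <- label_to_pm1(labs)
  acc <- cpp_searchlight_loo(B, as.integer(ypm), spheres,
                             clf$regularization_c, clf$fit_intercept,
                             1e-3, 1000L)
  values <- array(NA_real_, dims)
  values[vox_linear(centers, dims)] <- acc
  structure(list(values = values, valid_mask = valid, chance_level = 0.5,
                 sphere_spec = sphere, voxel_size_mm = betas$voxel_size_mm,
                 classifier = clf),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  cat(sprintf("<accuracy_map> %d valid voxels, mean accuracy %.3f (chance %.2f)\n",
              sum(x$valid_mask), mean(x$values[x$valid_mask]), x$chance_level))
  invisible(x)
}

#' Chance-centre and smooth an accuracy map
#'
#' Subtracts the theoretical chance level and smooths the centred map with
#' a Gaussian kernel, renormalising inside the validity mask so that the
#' smoothed values are not attenuated at mask boundaries. Invalid voxels
#' are excluded (NA).
#'
#' @param acc An [searchlight_map()] result.
#' @param smoothing A [smoothing_spec()]; the default is 6 mm FWHM with
#'   in-mask renormalisation.
#' @return 3D numeric array (NA outside the validity mask).
#' @export
center_and_smooth <- function(acc,
                              smoothing = smoothing_spec(6, "renormalize_in_mask")) {
  stopifnot(inherits(acc, "accuracy_map"))
  centred <- acc$values - acc$chance_level
  centred[!acc$valid_mask] <- 0
  gaussian_smooth(centred, smoothing, acc$voxel_size_mm, mask = acc$valid_mask)
}
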