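# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive (enumeration / direct loops), never the
# code path they check.

small_acq <- function(dims = c(8L, 8L, 6L), n_volumes = 120L, tr_s = 2)
  acquisition_spec(tr_s = tr_s, n_volumes = n_volumes, grid_dims = dims)

quick_design <- function(acq, n_per_condition = 4L, seed = 1L)
  make_block_design(n_per_condition, 8, 2, acq, lead_in_s = 0, seed = seed)

# brute-force closed-ball sphere offsets: enumerate a generous cube and keep
# offsets within the physical radius
brute_offsets <- function(radius_mm, spacing) {
  r <- ceiling(radius_mm / min(spacing)) + 1L
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  d <- sqrt((g$i * spacing[1])^2 + (g$j * spacing[2])^2 + (g$k * spacing[3])^2)
  m <- as.matrix(g[d <= radius_mm + 1e-9, ])
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# brute-force voxel-centre ellipsoid membership count
brute_ellipsoid_count <- function(dims, spacing, semi, ctr) {
  cnt <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      x <- ((i - 0.5) * spacing[1] - ctr[1]) / semi[1]
      y <- ((j - 0.5) * spacing[2] - ctr[2]) / semi[2]
      z <- ((k - 0.5) * spacing[3] - ctr[3]) / semi[3]
      if (x^2 + y^2 + z^2 <= 1) cnt <- cnt + 1L
    }
  cnt
}

# independent LOO via e1071 (libsvm), default linear SVM, no scaling
e1071_loo <- function(X, y) {
  y <- factor(y)
  correct <- 0L
  for (i in seq_len(nrow(X))) {
    m <- e1071::svm(X[-i, , drop = FALSE], y[-i], kernel = "linear",
                    cost = 1, scale = FALSE)
    if (predict(m, X[i, , drop = FALSE]) == y[i]) correct <- correct + 1L
  }
  correct / nrow(X)
}

# a small fitted beta_maps object from a simulated subject
quick_betas <- function(acq = small_acq(), truth = ground_truth_spec(),
                        gm = NULL, seed = 5L, n_per_condition = 4L) {
  gm <- gm %||% make_gm_mask(acq$grid_dims, acq$voxel_size_mm, "full")
  d <- quick_design(acq, n_per_condition)
  s <- simulate_subject(d, truth, "F", acq, gm, seed = seed)
  fit_glm(s, build_design_matrix(d, acq), gm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
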