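test_that("the canonical HRF peaks near 5 s with unit height", {
  # oracle: evaluate the double-gamma density difference on a fine grid
  tt <- seq(0, 32, by = 0.001)
  dens <- dgamma(tt, shape = 6, scale = 1) - dgamma(tt, shape = 16, scale = 1) / 6
  oracle_peak_t <- tt[which.max(dens)]

  k <- hrf_kernel(hrf_spec(sampling_dt_s = 0.1))
  expect_equal((which.max(k) - 1) * 0.1, oracle_peak_t, tolerance = 0.06)
  expect_equal(max(k), 1)
  expect_equal(k[1], 0)              # starts at zero
  expect_lt(min(k), 0)               # undershoot present
  expect_error(hrf_spec(peak_dispersion_s = 0), "dispersions")
})

test_that("the identity HRF is a discrete unit impulse", {
  k <- hrf_kernel(hrf_spec("identity"))
  expect_equal(k[1], 1)
  expect_true(all(k[-1] == 0))
})

test_that("design matrix has one column per block plus intercept, full rank", {
  acq <- acquisition_spec()
  d <- make_block_design(20, acquisition = acq, seed = 1)
  X <- build_design_matrix(d, acq)
  expect_equal(ncol(X$values), 41L)
  expect_equal(length(X$block_cols), 40L)
  expect_equal(qr(X$values)$rank, 41L)
  expect_equal(X$column_labels[41], "intercept")
})

test_that("identity-HRF block columns sample the boxcar and are orthogonal", {
  acq <- small_acq(n_volumes = 40L)
  d <- block_design(c(0, 10), 8, c("vocal", "non-vocal"), 2)
  X <- build_design_matrix(d, acq, hrf_spec("identity"),
                           include_intercept = FALSE)
  # block at onset 0, duration 8, TR 2 -> volumes 1:4 (t = 0, 2, 4, 6)
  expect_equal(X$values[, 1], c(rep(1, 4), rep(0, 36)))
  # non-overlapping boxcars are orthogonal
  expect_equal(sum(X$values[, 1] * X$values[, 2]), 0)
})

test_that("noise-free data give exact OLS recovery and zero residual variance", {
  acq <- small_acq()
  d <- quick_design(acq)
  X <- build_design_matrix(d, acq)
  set.seed(42)
  beta_true <- rnorm(ncol(X$values))
  y <- as.numeric(X$values %*% beta_true)
  dims <- acq$grid_dims
  dat <- array(rep(y, each = prod(dims)), dim = c(dims, acq$n_volumes))
  s <- structure(list(data = dat, acquisition = acq,
                      gm_mask = array(TRUE, dims), group_label = "F",
                      seed = 1L), class = "subject_series")
  b <- fit_glm(s, X)
  expect_equal(b$betas[3, 3, 3, ], beta_true[X$block_cols], tolerance = 1e-8)
  expect_lt(max(b$residual_variance), 1e-16)
  expect_equal(b$dof, acq$n_volumes - ncol(X$values))
})

test_that("an intercept-only fit of a constant recovers the constant", {
  acq <- small_acq(c(2L, 2L, 2L), 20L)
  d <- block_design(numeric(0), 8, character(0), 2)
  X <- build_design_matrix(d, acq)          # intercept only
  s <- structure(list(data = array(7, c(2, 2, 2, 20)), acquisition = acq,
                      gm_mask = array(TRUE, c(2, 2, 2)), group_label = "F",
                      seed = 1L), class = "subject_series")
  b <- fit_glm(s, X)
  expect_equal(b$dof, 19L)
  expect_equal(max(abs(b$residual_variance)), 0)
})

test_that("OLS residuals are orthogonal to every design column", {
  acq <- small_acq(c(4L, 4L, 3L))
  d <- quick_design(acq)
  truth <- ground_truth_spec(regions = list(region(c(2, 2, 2), 3)),
                             noise_sd = 1)
  s <- simulate_subject(d, truth, "F", acq,
                        make_gm_mask(acq$grid_dims, acq$voxel_size_mm, "full"),
                        seed = 8)
  X <- build_design_matrix(d, acq)
  b <- fit_glm(s, X)
  v <- c(2, 3, 2)
  y <- s$data[v[1], v[2], v[3], ]
  coef_v <- c(b$betas[v[1], v[2], v[3], ],
              qr.coef(qr(X$values), y)[-X$block_cols])
  # reconstruct the full coefficient vector via the block betas + refit check
  fit <- qr.fitted(qr(X$values), y)
  resid <- y - fit
  expect_lt(max(abs(crossprod(X$values, resid))), 1e-8)
})

test_that("degenerate designs are rejected", {
  acq <- small_acq(n_volumes = 30L)
  d <- block_design(c(0, 10), 8, c("vocal", "non-vocal"), 2)
  X <- build_design_matrix(d, acq)
  X$values <- cbind(X$values, dup = X$values[, 1])
  s <- structure(list(data = array(rnorm(4 * 30), c(2, 2, 1, 30)),
                      acquisition = acq, gm_mask = array(TRUE, c(2, 2, 1)),
                      group_label = "F", seed = 1L),
                 class = "subject_series")
  expect_error(fit_glm(s, X), "rank deficient")
  acq_short <- small_acq(c(2L, 2L, 1L), 3L)
  d2 <- block_design(numeric(0), 8, character(0), 2)
  X2 <- build_design_matrix(d2, acq_short, n_cosine_drift = 2L)
  s2 <- structure(list(data = array(rnorm(4 * 3), c(2, 2, 1, 3)),
                       acquisition = acq_short,
                       gm_mask = array(TRUE, c(2, 2, 1)),
                       group_label = "F", seed = 1L),
                  class = "subject_series")
  expect_error(fit_glm(s2, X2), "degrees of freedom")
})

test_that("noiseless planted amplitudes are recovered exactly by the GLM", {
  acq <- small_acq()
  gm <- make_gm_mask(acq$grid_dims, acq$voxel_size_mm, "full")
  d <- quick_design(acq)
  truth <- ground_truth_spec(regions = list(region(c(4, 4, 3), 4)),
                             univariate_amplitude = list(
                               F = c(vocal = 1, "non-vocal" = 0),
                               M = c(vocal = 1, "non-vocal" = 0)),
                             pattern_scale = c(F = 0, M = 0), noise_sd = 0)
  s <- simulate_subject(d, truth, "F", acq, gm, seed = 1)
  b <- fit_glm(s, build_design_matrix(d, acq), gm)
  vocal <- b$condition_labels == "vocal"
  expect_equal(b$betas[4, 4, 3, vocal], rep(1, sum(vocal)), tolerance = 1e-8)
  expect_equal(b$betas[4, 4, 3, !vocal], rep(0, sum(!vocal)), tolerance = 1e-8)
  # far from the region: all betas 0
  expect_lt(max(abs(b$betas[8, 8, 6, ])), 1e-8)
})

test_that("contrast maps follow the weights and the averaging oracle", {
  b <- quick_betas()
  nb <- dim(b$betas)[4]
  vocal <- b$condition_labels == "vocal"

  cm <- contrast_map(b)
  # oracle: direct averaging of vocal minus non-vocal betas
  dims <- dim(b$betas)[1:3]
  bb <- matrix(b$betas, prod(dims), nb)
  oracle <- rowMeans(bb[, vocal, drop = FALSE]) -
            rowMeans(bb[, !vocal, drop = FALSE])
  expect_equal(as.numeric(cm$values), oracle, tolerance = 1e-12)

  # zero-sum weights make the contrast invariant to a constant beta shift
  b_shift <- b
  b_shift$betas <- b$betas + 5
  expect_equal(contrast_map(b_shift)$values, cm$values, tolerance = 1e-10)

  # identical betas -> 0; vocal 1 / non-vocal 0 -> 1
  b_const <- b; b_const$betas[] <- 3
  expect_true(all(abs(contrast_map(b_const)$values) < 1e-12))
  b_cond <- b
  b_cond$betas <- array(rep(as.numeric(vocal), each = prod(dims)),
                        dim = dim(b$betas))
  expect_true(all(abs(contrast_map(b_cond)$values - 1) < 1e-12))

  expect_error(contrast_map(b, weights = c(1, -1)), "weights")
})
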