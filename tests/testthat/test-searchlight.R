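test_that("LOO accuracy is 1 on separable clouds and 0 on constant features", {
  set.seed(1)
  n <- 20
  X <- rbind(matrix(rnorm(n * 10, mean = 6), n),
             matrix(rnorm(n * 10, mean = -6), n))
  y <- rep(c("vocal", "non-vocal"), each = n)
  # margin check: the clouds are linearly separable along the mean direction
  proj <- rowMeans(X)
  expect_gt(min(proj[1:n]), max(proj[(n + 1):(2 * n)]))
  expect_equal(loo_cv_accuracy(X, y), 1)

  # constant rows: the held-out class is always the training minority
  expect_equal(loo_cv_accuracy(matrix(1, 40, 5), rep(c("a", "b"), each = 20)), 0)
})

test_that("LOO accuracy validates its inputs", {
  X <- matrix(rnorm(20), 10)
  expect_error(loo_cv_accuracy(X, rep("a", 10)), "two classes")
  Xn <- X; Xn[1] <- NaN
  expect_error(loo_cv_accuracy(Xn, rep(c("a", "b"), 5)), "finite")
  expect_error(loo_cv_accuracy(X[1, , drop = FALSE], "a"), "2 exemplars")
})

test_that("LOO accuracy is invariant to exemplar order and label swaps", {
  set.seed(7)
  X <- matrix(rnorm(30 * 8), 30)
  X[1:15, 1:3] <- X[1:15, 1:3] + 1
  y <- rep(c("vocal", "non-vocal"), each = 15)
  a0 <- loo_cv_accuracy(X, y)
  for (s in 1:3) {
    perm <- sample(30)
    expect_equal(loo_cv_accuracy(X[perm, ], y[perm]), a0)
  }
  y_sw <- ifelse(y == "vocal", "non-vocal", "vocal")
  expect_equal(loo_cv_accuracy(X, y_sw), a0)
})

test_that("accuracies are multiples of 1/n and deterministic", {
  set.seed(9)
  X <- matrix(rnorm(40 * 12), 40)
  y <- rep(c("a", "b"), 20)
  a1 <- loo_cv_accuracy(X, y)
  expect_equal(a1, loo_cv_accuracy(X, y))
  expect_equal(a1 * 40, round(a1 * 40))
})

test_that("pure-noise LOO accuracy sits at chance within Monte-Carlo error", {
  set.seed(23)
  y <- rep(c("vocal", "non-vocal"), each = 20)
  accs <- replicate(200, loo_cv_accuracy(matrix(rnorm(40 * 20), 40, 20), y))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("the hinge-loss solver agrees with an independent SVM (libsvm)", {
  skip_if_not_installed("e1071")
  set.seed(17)
  # separable problems: identical LOO accuracies
  for (rep in 1:5) {
    X <- rbind(matrix(rnorm(10 * 8, 4), 10), matrix(rnorm(10 * 8, -4), 10))
    y <- rep(c("a", "b"), each = 10)
    expect_equal(loo_cv_accuracy(X, y), e1071_loo(X, y))
  }
  # in-sample decision signs agree with libsvm away from the margin
  for (rep in 1:5) {
    X <- matrix(rnorm(24 * 10), 24)
    yf <- factor(rep(c("neg", "pos"), each = 12), levels = c("neg", "pos"))
    X[yf == "pos", 1:4] <- X[yf == "pos", 1:4] + 1.2
    m <- e1071::svm(X, yf, kernel = "linear", cost = 1, scale = FALSE)
    pred_lib <- as.character(predict(m, X))
    dec_lib <- as.numeric(attr(predict(m, X, decision.values = TRUE),
                               "decision.values"))
    dec_own <- voxlight:::cpp_svm_decision(X, ifelse(yf == "pos", 1L, -1L),
                                           1, TRUE, 1e-5, 5000L)
    pred_own <- ifelse(dec_own >= 0, "pos", "neg")
    clear <- abs(dec_lib) > 0.3
    expect_gt(sum(clear), 10)
    expect_equal(pred_own[clear], pred_lib[clear])
  }
  # full-problem agreement: the two formulations differ only in how the
  # intercept is regularised, so they may disagree on folds that sit on the
  # margin; with a clear class separation LOO accuracies must coincide to
  # within a couple of folds
  set.seed(18)
  diffs <- replicate(8, {
    X <- matrix(rnorm(24 * 10), 24)
    y <- rep(c("a", "b"), each = 12)
    X[1:12, 1:4] <- X[1:12, 1:4] + 2.5
    abs(loo_cv_accuracy(X, y) - e1071_loo(X, y))
  })
  expect_lte(max(diffs), 2 / 24 + 1e-9)
  expect_lte(mean(diffs), 1 / 24 + 1e-9)
})

test_that("searchlight map equals a brute-force per-voxel LOO loop", {
  acq <- small_acq(c(7L, 7L, 5L), 120L)
  gm <- make_gm_mask(acq$grid_dims, acq$voxel_size_mm, "ellipsoid")
  truth <- ground_truth_spec(regions = list(region(c(4, 4, 3), 4)),
                             pattern_scale = c(F = 0.05, M = 0),
                             noise_sd = 1, pattern_mode = "subject")
  b <- quick_betas(acq, truth, gm, seed = 21)
  sph <- sphere_spec(6, 0.5)
  acc <- searchlight_map(b, gm, sph)

  offs <- sphere_offsets(sph$radius_mm, acq$voxel_size_mm)
  dims <- acq$grid_dims
  labs <- b$condition_labels
  checked <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      ex <- extract_sphere(c(i, j, k), offs, gm, sph$min_gm_fraction)
      if (!ex$valid || nrow(ex$indices) == 0L) {
        expect_false(acc$valid_mask[i, j, k])
        next
      }
      expect_true(acc$valid_mask[i, j, k])
      lin <- voxlight:::vox_linear(ex$indices, dims)
      Xf <- t(vapply(seq_along(labs), function(bl) {
        vol <- b$betas[, , , bl]
        vol[lin]
      }, numeric(length(lin))))
      expect_equal(acc$values[i, j, k], loo_cv_accuracy(Xf, labs))
      checked <- checked + 1L
    }
  expect_gt(checked, 20L)
})

test_that("gray-matter gaps propagate to the validity mask", {
  acq <- small_acq(c(8L, 8L, 6L), 120L)
  gm <- make_gm_mask(acq$grid_dims, acq$voxel_size_mm, "full")
  gm[5:8, 5:8, 4:6] <- FALSE   # empty octant
  b <- quick_betas(acq, ground_truth_spec(), gm, seed = 3)
  acc <- searchlight_map(b, gm, sphere_spec(6, 0.5))
  expect_false(any(acc$valid_mask[6:8, 6:8, 5:6]))
  expect_true(any(acc$valid_mask))
})

test_that("chance centring and smoothing behave on constant maps", {
  acq <- small_acq(c(8L, 8L, 6L), 120L)
  gm <- make_gm_mask(acq$grid_dims, acq$voxel_size_mm, "full")
  b <- quick_betas(acq, ground_truth_spec(), gm, seed = 3)
  acc <- searchlight_map(b, gm)

  acc$values[acc$valid_mask] <- 0.5
  out <- center_and_smooth(acc)
  expect_lt(max(abs(out[acc$valid_mask])), 1e-12)

  acc$values[acc$valid_mask] <- 1
  out1 <- center_and_smooth(acc)
  expect_equal(out1[4, 4, 3], 0.5, tolerance = 1e-9)

  # single above-chance voxel: the smoothed excess is conserved in the
  # mask interior (kernel normalisation + linearity)
  acc$values[acc$valid_mask] <- 0.5
  acc$values[4, 4, 3] <- 0.9
  out2 <- center_and_smooth(acc)
  expect_equal(sum(out2[acc$valid_mask]), 0.4, tolerance = 0.02)
})
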