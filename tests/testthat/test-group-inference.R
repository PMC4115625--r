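null_maps <- function(n, dims = c(4L, 4L, 3L), seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(rnorm(prod(dims)), dims))
}

test_that("five identical positive maps give exhaustive p = 1/32 everywhere", {
  dims <- c(3L, 3L, 2L)
  maps <- lapply(1:5, function(i) array(1, dims))
  mask <- array(TRUE, dims)
  res <- one_sample_perm_test(maps, mask, inference_spec(tail = "greater"))
  expect_equal(res$n_permutations_used, 32L)
  expect_true(all(res$p_unc_map == 1 / 32))
  expect_true(all(res$p_fwe_map == 1 / 32))
})

test_that("all-zero maps return the degenerate convention t = 0, p = 1", {
  dims <- c(3L, 3L, 2L)
  maps <- lapply(1:5, function(i) array(0, dims))
  res <- one_sample_perm_test(maps, array(TRUE, dims), inference_spec())
  expect_true(all(res$t_map == 0))
  expect_true(all(res$p_unc_map == 1))
  expect_true(all(res$p_fwe_map == 1))
})

test_that("the observed one-sample t matches the closed-form Student statistic", {
  maps <- null_maps(8, seed = 5)
  mask <- array(TRUE, dim(maps[[1]]))
  res <- one_sample_perm_test(maps, mask, inference_spec(tail = "greater"))
  v <- c(2, 3, 1)
  x <- vapply(maps, function(m) m[v[1], v[2], v[3]], numeric(1))
  expect_equal(res$t_map[v[1], v[2], v[3]],
               unname(t.test(x)$statistic), tolerance = 1e-10)
})

test_that("Monte-Carlo p-values converge to the exhaustive enumeration", {
  maps <- null_maps(6, dims = c(3L, 3L, 1L), seed = 9)
  mask <- array(TRUE, c(3, 3, 1))
  ex <- one_sample_perm_test(maps, mask,
                             inference_spec(exhaustive_if_feasible = TRUE))
  expect_equal(ex$n_permutations_used, 64L)
  mc <- one_sample_perm_test(maps, mask,
                             inference_spec(n_permutations = 8000L,
                                            exhaustive_if_feasible = FALSE,
                                            seed = 3))
  expect_lt(max(abs(mc$p_unc_map - ex$p_unc_map)), 0.03)
  expect_lt(max(abs(mc$p_fwe_map - ex$p_fwe_map)), 0.03)
})

test_that("p-value bounds hold: p_fwe >= p_unc >= 1/N", {
  for (tail in c("greater", "less", "two_sided")) {
    maps <- null_maps(7, seed = match(tail, c("greater", "less", "two_sided")))
    mask <- array(TRUE, dim(maps[[1]]))
    res <- one_sample_perm_test(maps, mask, inference_spec(tail = tail))
    expect_true(all(res$p_fwe_map >= res$p_unc_map))
    expect_true(all(res$p_unc_map >= 1 / res$n_permutations_used))
    expect_true(all(res$p_fwe_map <= 1))
  }
})

test_that("two-sample t is antisymmetric under group swap", {
  a <- null_maps(5, seed = 11)
  b <- lapply(null_maps(6, seed = 12), function(m) m + 0.4)
  mask <- array(TRUE, dim(a[[1]]))
  sp <- inference_spec(tail = "two_sided", seed = 2)
  r1 <- two_sample_perm_test(a, b, mask, sp)
  r2 <- two_sample_perm_test(b, a, mask, sp)
  expect_equal(r1$t_map, -r2$t_map, tolerance = 1e-12)
})

test_that("exhaustive two-sample p equals the brute-force count ratio", {
  dims <- c(2L, 2L, 1L)
  set.seed(13)
  base <- lapply(1:8, function(i) array(rnorm(prod(dims), sd = 0.1), dims))
  a <- lapply(base[1:4], function(m) m + 5)   # large shift
  b <- base[5:8]
  mask <- array(TRUE, dims)
  res <- two_sample_perm_test(a, b, mask, inference_spec(tail = "greater"))
  expect_equal(res$n_permutations_used, choose(8, 4))

  # independent oracle: enumerate every assignment, pooled-variance t
  Y <- t(vapply(c(a, b), function(m) as.numeric(m), numeric(prod(dims))))
  combs <- combn(8, 4)
  pooled_t <- function(xa, xb) {
    sp2 <- ((length(xa) - 1) * var(xa) + (length(xb) - 1) * var(xb)) /
           (length(xa) + length(xb) - 2)
    (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / length(xa) + 1 / length(xb)))
  }
  for (v in seq_len(prod(dims))) {
    t_obs <- pooled_t(Y[1:4, v], Y[5:8, v])
    maxs <- apply(combs, 2, function(idx) {
      max(vapply(seq_len(prod(dims)), function(w)
        pooled_t(Y[idx, w], Y[-idx, w]), numeric(1)))
    })
    p_fwe_oracle <- mean(maxs >= t_obs)
    lin <- arrayInd(v, dims)
    expect_equal(res$p_fwe_map[lin[1], lin[2], lin[3]], p_fwe_oracle,
                 tolerance = 1e-12)
  }
})

test_that("group tests validate their inputs", {
  dims <- c(3L, 3L, 1L)
  mask <- array(TRUE, dims)
  expect_error(one_sample_perm_test(null_maps(1, dims), mask, inference_spec()),
               "2 subjects")
  expect_error(one_sample_perm_test(null_maps(3), array(FALSE, c(4, 4, 3)),
                                    inference_spec()), "empty")
  expect_error(two_sample_perm_test(null_maps(1), null_maps(3),
                                    array(TRUE, c(4, 4, 3)), inference_spec()),
               "2 subjects per group")
  expect_error(one_sample_perm_test(null_maps(20), array(TRUE, c(4, 4, 3)),
                                    inference_spec(exhaustive_if_feasible = FALSE,
                                                   n_permutations = 50L)),
               "seed")
})

test_that("conjunction mask intersects the sub-threshold sets strictly", {
  maps_sig <- lapply(1:6, function(i) array(1, c(3, 3, 2)) +
                       array(rnorm(18, sd = 0.01), c(3, 3, 2)))
  maps_null <- null_maps(6, c(3L, 3L, 2L), seed = 21)
  mask <- array(TRUE, c(3, 3, 2))
  sp <- inference_spec(tail = "greater")
  ra <- one_sample_perm_test(maps_sig, mask, sp)
  rb <- one_sample_perm_test(maps_null, mask, sp)
  expect_equal(sum(conjunction_mask(ra, rb, 0.05) &
                   !(rb$p_unc_map < 0.05)), 0L)
  expect_equal(conjunction_mask(ra, ra, 0.05),
               array(ra$p_unc_map < 0.05, c(3, 3, 2)))
  rc <- one_sample_perm_test(null_maps(3, c(4L, 4L, 3L), seed = 2),
                             array(TRUE, c(4, 4, 3)), sp)
  expect_error(conjunction_mask(ra, rc), "mismatch")
})

test_that("clusterize separates components by connectivity and finds peaks", {
  dims <- c(5L, 5L, 3L)
  tm <- array(0, dims)
  tm[2, 2, 2] <- 3
  one <- clusterize(tm, threshold_t = 1, connectivity = 18L)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$peak_x, one$peak_y, one$peak_z), c(2L, 2L, 2L))
  expect_equal(one$size_voxels, 1L)

  # two voxels sharing only a corner: one cluster at 26, two at 6
  tm2 <- array(0, dims)
  tm2[2, 2, 1] <- 2
  tm2[3, 3, 2] <- 4
  expect_equal(nrow(clusterize(tm2, threshold_t = 1, connectivity = 26L)), 1L)
  expect_equal(nrow(clusterize(tm2, threshold_t = 1, connectivity = 6L)), 2L)

  expect_equal(nrow(clusterize(array(0, dims), threshold_t = 1)), 0L)

  # peak tie-break: first in scan order among equal maxima
  tm3 <- array(0, dims)
  tm3[2:3, 2, 2] <- 5
  tie <- clusterize(tm3, threshold_t = 1, connectivity = 6L)
  expect_equal(c(tie$peak_x, tie$peak_y, tie$peak_z), c(2L, 2L, 2L))
})

test_that("Cohen's d follows the pooled-variance formula", {
  expect_equal(cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(1, 5, 2, 4); b <- c(0, 1, 3, 2)
  expect_equal(cohens_d(3 * a, 3 * b), cohens_d(a, b))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "undefined")
  expect_error(cohens_d(1, c(1, 2)), "2 values")
})
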