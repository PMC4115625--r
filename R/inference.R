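#' Second-level inference specification
#'
#' Controls the nonparametric group tests: number of permutations,
#' family-wise error level (voxel-level maximum statistic), the uncorrected
#' level used for conjunction masks, the test tail, and whether the full
#' permutation group is enumerated when feasible (all `2^n` sign flips for
#' `n <= 14` subjects in the one-sample test; all label reassignments up to
#' `exhaustive_limit` in the two-sample test). The identity permutation is
#' always part of the null, so p-values are bounded below by
#' `1 / n_permutations_used`.
#'
#' @param n_permutations Number of Monte-Carlo permutations, identity
#'   included (default 10000).
#' @param alpha_fwe FWE-corrected significance level (default 0.05).
#' @param mask_alpha_uncorrected Uncorrected level for conjunction masks
#'   (default 0.01, strict `<`).
#' @param tail `"greater"`, `"less"` or `"two_sided"`.
#' @param seed Integer seed; mandatory for any Monte-Carlo run.
#' @param exhaustive_if_feasible Enumerate the full permutation group when
#'   small enough (default TRUE).
#' @param exhaustive_limit Largest enumerable permutation count for the
#'   two-sample test (default 20000).
#' @return An object of class `inference_spec`.
#' @export
inference_spec <- function(n_permutations = 10000L, alpha_fwe = 0.05,
                           mask_alpha_uncorrected = 0.01,
                           tail = c("greater", "less", "two_sided"),
                           seed = NULL, exhaustive_if_feasible = TRUE,
                           exhaustive_limit = 20000L) {
  if (n_permutations < 1) stop_("`n_permutations` must be >= 1")
  if (alpha_fwe <= 0 || alpha_fwe >= 1 ||
      mask_alpha_uncorrected <= 0 || mask_alpha_uncorrected >= 1)
    stop_("alpha levels must lie in (0, 1)")
  structure(list(n_permutations = as.integer(n_permutations),
                 alpha_fwe = alpha_fwe,
                 mask_alpha_uncorrected = mask_alpha_uncorrected,
                 tail = match.arg(tail), seed = seed,
                 exhaustive_if_feasible = isTRUE(exhaustive_if_feasible),
                 exhaustive_limit = as.integer(exhaustive_limit)),
            class = "inference_spec")
}

# subject maps (list of 3D arrays or a 4D array) -> n x V matrix on the mask
maps_to_matrix <- function(maps, mask) {
  if (is.array(maps) && length(dim(maps)) == 4L)
    maps <- lapply(seq_len(dim(maps)[4]), function(i) maps[, , , i])
  dims <- dim(mask)
  idx <- which(mask)
  Y <- t(vapply(maps, function(m) {
    if (!identical(dim(m), dims)) stop_("subject map grid mismatch")
    m[idx]
  }, numeric(length(idx))))
  if (any(!is.finite(Y)))
    stop_("subject maps contain non-finite values inside the mask")
  Y
}

# t statistic rows for sign-flip matrix S (P x n): one-sample t vs 0.
# sumsq is invariant under sign flips.
t_one_sample <- function(S, Y, sumsq, n) {
  m <- (S %*% Y) / n
  v <- (matrix(sumsq, nrow(S), length(sumsq), byrow = TRUE) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- m / sqrt(v / n)
  deg <- v < 1e-20
  t[deg] <- ifelse(abs(m[deg]) < 1e-12, 0, sign(m[deg]) * Inf)
  t
}

apply_tail <- function(t, tail) {
  switch(tail, greater = t, less = -t, two_sided = abs(t))
}

finish_perm_test <- function(stat_obs, t_obs_signed, unc_count, fwe_count,
                             n_used, maxs, mask, spec, test, n_subjects) {
  dims <- dim(mask)
  mk <- function(v) { a <- array(NA_real_, dims); a[which(mask)] <- v; a }
  structure(list(t_map = mk(t_obs_signed), p_fwe_map = mk(fwe_count / n_used),
                 p_unc_map = mk(unc_count / n_used),
                 analysis_mask = mask, n_permutations_used = n_used,
                 max_stat_distribution = maxs, tail = spec$tail,
                 test = test, n_subjects = n_subjects),
            class = "group_stat_result")
}

#' @export
print.group_stat_result <- function(x, ...) {
  cat(sprintf("<group_stat_result> %s test (%s tail), n = %s, %d permutations, %d voxels, min p_fwe %.4g\n",
              x$test, x$tail, paste(x$n_subjects, collapse = " + "),
              x$n_permutations_used, sum(x$analysis_mask),
              min(x$p_fwe_map, na.rm = TRUE)))
  invisible(x)
}

#' One-sample permutation test with max-statistic FWE correction
#'
#' Voxelwise one-sample t test of the subject maps against 0, with the null
#' built by random sign flips of whole subject maps (the identity flip is
#' always included). `p_fwe(v)` is the proportion of permutations whose
#' maximum statistic over the mask reaches the observed statistic at `v`;
#' `p_unc(v)` comes from the voxel's own permutation distribution. With
#' `exhaustive_if_feasible` and `n <= 14` subjects all `2^n` flips are
#' enumerated. Degenerate voxels (zero variance) yield `t = 0, p = 1` when
#' the mean is also 0, and an infinite statistic otherwise.
#'
#' @param maps List of 3D subject maps (or 4D array, subjects last).
#' @param mask Logical 3D analysis mask.
#' @param spec An [inference_spec()].
#' @return An object of class `group_stat_result` with `t_map`,
#'   `p_fwe_map`, `p_unc_map`, `analysis_mask`, `n_permutations_used` and
#'   `max_stat_distribution`.
#' @export
one_sample_perm_test <- function(maps, mask, spec = inference_spec()) {
  stopifnot(inherits(spec, "inference_spec"))
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop_("empty analysis mask")
  Y <- maps_to_matrix(maps, mask)
  n <- nrow(Y)
  if (n < 2L) stop_("at least 2 subjects are required")
  sumsq <- colSums(Y^2)

  exhaustive <- spec$exhaustive_if_feasible && n <= 14L
  if (exhaustive) {
    P <- 2L^n
    signs_of <- function(rows) {
      # rows are 0-based permutation codes; bit b flips subject b + 1
      S <- matrix(1, length(rows), n)
      for (b in seq_len(n))
        S[, b] <- ifelse(bitwAnd(rows, bitwShiftL(1L, b - 1L)) > 0L, -1, 1)
      S
    }
    codes <- 0:(P - 1L)
  } else {
    if (is.null(spec$seed))
      stop_("`seed` is mandatory for Monte-Carlo permutation runs")
    P <- spec$n_permutations
    Sall <- with_seed(spec$seed,
      rbind(rep(1, n),
            matrix(sample(c(-1, 1), (P - 1L) * n, replace = TRUE), P - 1L, n)))
  }

  # the identity permutation is the first row of the enumeration; the
  # observed statistics are taken from it inside the first chunk so that
  # they are bit-identical to that permutation's row (guaranteeing
  # p >= 1/N without tolerance games)
  t_obs_signed <- NULL
  stat_obs <- NULL
  unc_count <- NULL
  maxs <- numeric(P)
  chunk <- 512L
  done <- 0L
  while (done < P) {
    take <- min(chunk, P - done)
    S <- if (exhaustive) signs_of(codes[(done + 1L):(done + take)])
         else Sall[(done + 1L):(done + take), , drop = FALSE]
    st_signed <- t_one_sample(S, Y, sumsq, n)
    st <- apply_tail(st_signed, spec$tail)
    if (done == 0L) {
      t_obs_signed <- st_signed[1L, ]
      stat_obs <- st[1L, ]
      unc_count <- numeric(length(stat_obs))
    }
    maxs[(done + 1L):(done + take)] <- apply(st, 1L, max)
    unc_count <- unc_count +
      colSums(st >= matrix(stat_obs, take, length(stat_obs), byrow = TRUE))
    done <- done + take
  }
  fwe_count <- vapply(stat_obs, function(s) sum(maxs >= s), numeric(1))
  finish_perm_test(stat_obs, t_obs_signed, unc_count, fwe_count,
                   as.integer(P), maxs, mask, spec, "one-sample", n)
}

#' Two-sample permutation test with max-statistic FWE correction
#'
#' Voxelwise pooled-variance two-sample t (group A minus group B), with the
#' null built by random reassignment of group labels (identity included).
#' When feasible, all `choose(nA + nB, nA)` assignments are enumerated.
#'
#' @param maps_a,maps_b Lists of 3D subject maps (or 4D arrays) per group.
#' @param mask Logical 3D analysis mask.
#' @param spec An [inference_spec()].
#' @return An object of class `group_stat_result`.
#' @export
two_sample_perm_test <- function(maps_a, maps_b, mask, spec = inference_spec()) {
  stopifnot(inherits(spec, "inference_spec"))
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop_("empty analysis mask")
  Ya <- maps_to_matrix(maps_a, mask)
  Yb <- maps_to_matrix(maps_b, mask)
  na <- nrow(Ya); nb <- nrow(Yb)
  if (na < 2L || nb < 2L) stop_("at least 2 subjects per group are required")
  Y <- rbind(Ya, Yb)
  n <- na + nb
  Y2 <- Y^2
  tot_sum <- colSums(Y)
  tot_ssq <- colSums(Y2)

  t_two_sample <- function(Z) {
    # Z: P x n indicator of group-A membership
    sa <- Z %*% Y
    qa <- Z %*% Y2
    ma <- sa / na
    mb <- (matrix(tot_sum, nrow(Z), ncol(Y), byrow = TRUE) - sa) / nb
    ssa <- qa - na * ma^2
    ssb <- (matrix(tot_ssq, nrow(Z), ncol(Y), byrow = TRUE) - qa) - nb * mb^2
    pv <- (ssa + ssb) / (n - 2)
    pv[pv < 0] <- 0
    t <- (ma - mb) / sqrt(pv * (1 / na + 1 / nb))
    deg <- pv < 1e-20
    d <- ma[deg] - mb[deg]
    t[deg] <- ifelse(abs(d) < 1e-12, 0, sign(d) * Inf)
    t
  }

  n_all <- choose(n, na)
  exhaustive <- spec$exhaustive_if_feasible && n_all <= spec$exhaustive_limit
  if (exhaustive) {
    combs <- combn(n, na)
    P <- ncol(combs)
    Zall <- matrix(0, P, n)
    Zall[cbind(rep(seq_len(P), each = na), as.vector(combs))] <- 1
    # put the identity assignment first
    ident <- which(apply(Zall[, seq_len(na), drop = FALSE] == 1, 1L, all))[1]
    Zall <- Zall[c(ident, setdiff(seq_len(P), ident)), , drop = FALSE]
  } else {
    if (is.null(spec$seed))
      stop_("`seed` is mandatory for Monte-Carlo permutation runs")
    P <- spec$n_permutations
    Zall <- with_seed(spec$seed, {
      Z <- matrix(0, P, n)
      Z[1, seq_len(na)] <- 1
      for (p in 2:P) Z[p, sample(n, na)] <- 1
      Z
    })
  }

  # observed statistics come from the identity row inside the first chunk
  # (bit-identical to the permutation enumeration, so p >= 1/N holds)
  t_obs_signed <- NULL
  stat_obs <- NULL
  unc_count <- NULL
  maxs <- numeric(P)
  chunk <- 512L
  done <- 0L
  while (done < P) {
    take <- min(chunk, P - done)
    st_signed <- t_two_sample(Zall[(done + 1L):(done + take), , drop = FALSE])
    st <- apply_tail(st_signed, spec$tail)
    if (done == 0L) {
      t_obs_signed <- st_signed[1L, ]
      stat_obs <- st[1L, ]
      unc_count <- numeric(length(stat_obs))
    }
    maxs[(done + 1L):(done + take)] <- apply(st, 1L, max)
    unc_count <- unc_count +
      colSums(st >= matrix(stat_obs, take, length(stat_obs), byrow = TRUE))
    done <- done + take
  }
  fwe_count <- vapply(stat_obs, function(s) sum(maxs >= s), numeric(1))
  finish_perm_test(stat_obs, t_obs_signed, unc_count, fwe_count,
                   as.integer(P), maxs, mask, spec, "two-sample", c(na, nb))
}

#' Conjunction mask from two group results
#'
#' Voxels whose uncorrected permutation p-value is strictly below
#' `alpha_unc` in both inputs; used to restrict between-group tests to
#' voxels decodable above chance in both groups.
#'
#' @param result_a,result_b `group_stat_result` objects on the same grid.
#' @param alpha_unc Uncorrected level (default 0.01).
#' @return Logical 3D mask.
#' @export
conjunction_mask <- function(result_a, result_b, alpha_unc = 0.01) {
  stopifnot(inherits(result_a, "group_stat_result"),
            inherits(result_b, "group_stat_result"))
  if (!identical(dim(result_a$p_unc_map), dim(result_b$p_unc_map)))
    stop_("grid mismatch between the two results")
  m <- (result_a$p_unc_map < alpha_unc) & (result_b$p_unc_map < alpha_unc)
  m[is.na(m)] <- FALSE
  m
}
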