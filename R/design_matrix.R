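#' Build the per-block GLM design matrix
#'
#' One regressor per block: the block's boxcar is laid out on a fine time
#' grid (`sampling_dt_s` of the HRF spec), convolved with the HRF kernel
#' normalised to unit integral (Riemann-sum convolution, so amplitudes do
#' not depend on the fine step) and sampled at the volume acquisition times
#' `t = k * tr_s`. Unit-integral normalisation is the standard regression
#' convention: a sustained response of amplitude `a` in data units yields a
#' regressor plateau near 1 and hence betas near `a`. With the `identity`
#' HRF the regressor is the sampled boxcar itself. Optional discrete-cosine
#' drift columns and an intercept follow the block columns.
#'
#' @param design A [block_design()].
#' @param acquisition An [acquisition_spec()].
#' @param hrf An [hrf_spec()].
#' @param n_cosine_drift Number of cosine drift regressors (default 0).
#' @param include_intercept Add a constant column (default TRUE).
#' @return An object of class `design_matrix` with fields `values`
#'   (`n_volumes x n_regressors`), `column_labels`, `block_condition` (the
#'   condition of each block column) and `block_cols` (their indices).
#' @examples
#' X <- build_design_matrix(make_block_design(seed = 1), acquisition_spec())
#' dim(X$values) # 310 x 41
#' @export
build_design_matrix <- function(design, acquisition, hrf = hrf_spec(),
                                n_cosine_drift = 0L, include_intercept = TRUE) {
  stopifnot(inherits(design, "block_design"),
            inherits(acquisition, "acquisition_spec"))
  check_design_fits(design, acquisition)
  nb <- n_blocks(design)
  nv <- acquisition$n_volumes
  vol_t <- (seq_len(nv) - 1) * acquisition$tr_s

  if (nb > 0L) {
    if (hrf$kind == "identity") {
      cols <- vapply(seq_len(nb), function(b) {
        on <- design$block_onsets_s[b]
        as.numeric(vol_t >= on - 1e-9 & vol_t < on + design$block_duration_s - 1e-9)
      }, numeric(nv))
    } else {
      dt <- hrf$sampling_dt_s
      kern <- hrf_kernel(hrf)
      kern <- kern / (sum(kern) * dt)        # unit integral for regression
      n_fine <- ceiling(run_duration_s(acquisition) / dt) + 1L
      fine_t <- (seq_len(n_fine) - 1) * dt
      vol_idx <- round(vol_t / dt) + 1L
      cols <- vapply(seq_len(nb), function(b) {
        on <- design$block_onsets_s[b]
        box <- as.numeric(fine_t >= on - 1e-9 &
                          fine_t < on + design$block_duration_s - 1e-9)
        conv <- stats::convolve(box, rev(kern), type = "open") * dt
        conv[vol_idx]
      }, numeric(nv))
    }
  } else {
    cols <- matrix(numeric(0), nrow = nv, ncol = 0)
  }
  labels <- if (nb > 0L) sprintf("block_%02d", seq_len(nb)) else character(0)

  if (n_cosine_drift > 0L) {
    k <- seq_len(n_cosine_drift)
    drift <- sapply(k, function(kk)
      cos(pi * kk * (seq_len(nv) - 0.5) / nv))
    cols <- cbind(cols, drift)
    labels <- c(labels, sprintf("drift_%02d", k))
  }
  if (include_intercept) {
    cols <- cbind(cols, 1)
    labels <- c(labels, "intercept")
  }
  colnames(cols) <- labels

  if (ncol(cols) > 0L) {
    qr_x <- qr(cols)
    if (qr_x$rank < ncol(cols)) {
      bad <- labels[qr_x$pivot[(qr_x$rank + 1L):ncol(cols)]]
      stop_("design matrix is rank deficient; offending columns: %s",
            paste(bad, collapse = ", "))
    }
  }
  structure(list(values = cols, column_labels = labels,
                 block_condition = design$condition_labels,
                 block_cols = seq_len(nb)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d volumes x %d regressors (%d block columns)\n",
              nrow(x$values), ncol(x$values), length(x$block_cols)))
  invisible(x)
}
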