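#' Build a vocal / non-vocal block design
#'
#' Lays out `2 * n_per_condition` stimulation blocks of equal duration on a
#' regular grid of onsets (`lead_in_s`, then one block every
#' `block_dur_s + ibi_s` seconds) and assigns condition labels by a seeded
#' random permutation with equal counts per condition. The default paradigm
#' is 20 vocal + 20 non-vocal blocks of 8 s separated by 2 s, i.e. 400 s of
#' paradigm inside a 620 s run; the remaining rest is left at the end of the
#' run (after the configurable lead-in).
#'
#' @param n_per_condition Number of blocks per condition (>= 0).
#' @param block_dur_s Block duration in seconds.
#' @param ibi_s Inter-block interval in seconds.
#' @param acquisition An [acquisition_spec()]; the paradigm must fit in the run.
#' @param lead_in_s Rest before the first block, seconds.
#' @param seed Integer seed for the condition order.
#' @return An object of class `block_design` with fields `block_onsets_s`,
#'   `block_duration_s`, `condition_labels` (in `c("vocal", "non-vocal")`)
#'   and `inter_block_interval_s`.
#' @examples
#' d <- make_block_design(seed = 1)
#' table(d$condition_labels)
#' @export
make_block_design <- function(n_per_condition = 20L, block_dur_s = 8,
                              ibi_s = 2, acquisition = acquisition_spec(),
                              lead_in_s = 10, seed = 1L) {
  if (n_per_condition < 0) stop_("`n_per_condition` must be >= 0")
  n_per_condition <- as.integer(n_per_condition)
  block_dur_s <- check_scalar_num(block_dur_s, "block_dur_s", 0, strict = TRUE)
  ibi_s <- check_scalar_num(ibi_s, "ibi_s", 0)
  lead_in_s <- check_scalar_num(lead_in_s, "lead_in_s", 0)
  stopifnot(inherits(acquisition, "acquisition_spec"))

  n_blocks <- 2L * n_per_condition
  total <- lead_in_s + n_blocks * (block_dur_s + ibi_s)
  run <- run_duration_s(acquisition)
  if (total > run)
    stop_("paradigm (%g s) exceeds the run (%g s) by %g s",
          total, run, total - run)

  if (n_blocks == 0L) {
    onsets <- numeric(0)
    labels <- character(0)
  } else {
    onsets <- lead_in_s + (seq_len(n_blocks) - 1) * (block_dur_s + ibi_s)
    labels <- with_seed(seed, sample(rep(c("vocal", "non-vocal"),
                                         each = n_per_condition)))
  }
  block_design(onsets, block_dur_s, labels, ibi_s)
}

#' Low-level block design constructor
#'
#' Validates and assembles a block design from explicit onsets and labels.
#' Onsets must be strictly increasing and consecutive onsets must be at
#' least `block_duration_s + inter_block_interval_s` apart.
#'
#' @param block_onsets_s Numeric vector of block onsets in seconds.
#' @param block_duration_s Common block duration, seconds.
#' @param condition_labels Character vector over blocks, values in
#'   `c("vocal", "non-vocal")`.
#' @param inter_block_interval_s Inter-block interval, seconds.
#' @return An object of class `block_design`.
#' @export
block_design <- function(block_onsets_s, block_duration_s, condition_labels,
                         inter_block_interval_s) {
  block_duration_s <- check_scalar_num(block_duration_s, "block_duration_s",
                                       0, strict = TRUE)
  inter_block_interval_s <- check_scalar_num(inter_block_interval_s,
                                             "inter_block_interval_s", 0)
  if (length(block_onsets_s) != length(condition_labels))
    stop_("one condition label per block is required")
  if (!all(condition_labels %in% c("vocal", "non-vocal")))
    stop_("condition labels must be 'vocal' or 'non-vocal'")
  if (length(block_onsets_s) > 1L) {
    gaps <- diff(block_onsets_s)
    if (any(gaps <= 0)) stop_("block onsets must be strictly increasing")
    if (any(gaps < block_duration_s + inter_block_interval_s - 1e-9))
      stop_("consecutive onsets closer than block duration + interval")
  }
  structure(list(block_onsets_s = as.numeric(block_onsets_s),
                 block_duration_s = block_duration_s,
                 condition_labels = as.character(condition_labels),
                 inter_block_interval_s = inter_block_interval_s),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  n <- length(x$block_onsets_s)
  cat(sprintf("<block_design> %d blocks (%s), %gs each, %gs interval\n", n,
              paste(sprintf("%d %s", as.integer(table(x$condition_labels)),
                            names(table(x$condition_labels))), collapse = " + "),
              x$block_duration_s, x$inter_block_interval_s))
  invisible(x)
}

n_blocks <- function(design) length(design$block_onsets_s)

# check that the last block ends inside the run
check_design_fits <- function(design, acquisition) {
  if (n_blocks(design) == 0L) return(invisible(TRUE))
  last_end <- max(design$block_onsets_s) + design$block_duration_s
  run <- run_duration_s(acquisition)
  if (last_end > run)
    stop_("last block ends at %g s, %g s past the end of the run (%g s)",
          last_end, last_end - run, run)
  invisible(TRUE)
}
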