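#' Hemodynamic response function specification
#'
#' The canonical double-gamma form: a gamma density peaking around 5 s minus
#' a scaled gamma density modelling the late undershoot,
#' `h(t) = g(t; peak_delay, peak_dispersion) -
#'         undershoot_ratio * g(t; undershoot_delay, undershoot_dispersion)`,
#' sampled at `sampling_dt_s` and normalised to unit peak. The `identity`
#' kind is the Dirac identity of convolution (a discrete unit impulse),
#' useful for tests where regressors should equal the raw boxcars.
#'
#' @param kind `"canonical_double_gamma"` or `"identity"`.
#' @param peak_delay_s,undershoot_delay_s Gamma delays (shape * scale), s.
#' @param peak_dispersion_s,undershoot_dispersion_s Gamma dispersions
#'   (scales), s; must be positive.
#' @param undershoot_ratio Relative undershoot amplitude.
#' @param sampling_dt_s Fine sampling step for convolution, s.
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(kind = c("canonical_double_gamma", "identity"),
                     peak_delay_s = 6, undershoot_delay_s = 16,
                     peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                     undershoot_ratio = 1 / 6, sampling_dt_s = 0.1) {
  kind <- match.arg(kind)
  if (peak_dispersion_s <= 0 || undershoot_dispersion_s <= 0)
    stop_("dispersions must be positive")
  sampling_dt_s <- check_scalar_num(sampling_dt_s, "sampling_dt_s", 0,
                                    strict = TRUE)
  structure(list(kind = kind, peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_dispersion_s = peak_dispersion_s,
                 undershoot_dispersion_s = undershoot_dispersion_s,
                 undershoot_ratio = undershoot_ratio,
                 sampling_dt_s = sampling_dt_s),
            class = "hrf_spec")
}

#' Sample the HRF kernel
#'
#' Evaluates the kernel of an [hrf_spec()] on `t = 0, dt, 2 dt, ...,
#' duration_s`. The canonical kernel starts at 0, rises to its unit peak
#' near 5 s and shows a negative undershoot; the identity kernel is 1 at
#' `t = 0` and 0 elsewhere.
#'
#' @param spec An [hrf_spec()].
#' @param duration_s Kernel support, seconds (default 32 covers the
#'   canonical shape).
#' @return Numeric vector of kernel samples.
#' @examples
#' k <- hrf_kernel(hrf_spec(), 32)
#' which.max(k) # peak near t = 5 s at dt = 0.1
#' @export
hrf_kernel <- function(spec = hrf_spec(), duration_s = 32) {
  dt <- spec$sampling_dt_s
  t <- seq(0, duration_s, by = dt)
  if (spec$kind == "identity")
    return(c(1, rep(0, length(t) - 1L)))
  h <- dgamma(t, shape = spec$peak_delay_s / spec$peak_dispersion_s,
              scale = spec$peak_dispersion_s) -
       spec$undershoot_ratio *
       dgamma(t, shape = spec$undershoot_delay_s / spec$undershoot_dispersion_s,
              scale = spec$undershoot_dispersion_s)
  pk <- max(h)
  if (pk <= 0) stop_("kernel has non-positive peak; check the parameters")
  h / pk
}
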