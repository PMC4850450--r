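#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical double-gamma HRF: a gamma-density peak (mode near
#' 5 s) minus a slower gamma-density undershoot (mode near 15 s) at one sixth
#' amplitude. The kernel is normalized so that the continuous-time peak equals
#' 1, which makes the sampled curve independent of the sampling rate (the same
#' underlying function is evaluated on every grid).
#'
#' @param fs Sampling rate in Hz. Must be positive.
#' @param duration_s Kernel duration in seconds. Must be positive.
#' @param peak_shape,undershoot_shape Shape parameters of the two gamma
#'   densities (rate 1 per second). Defaults place the peak at 5 s and the
#'   undershoot trough near 15 s.
#' @param undershoot_ratio Amplitude ratio of undershoot to peak.
#' @return Numeric vector of `round(duration_s * fs)` samples starting at
#'   t = 0 (where the kernel is 0), with maximum 1 at the peak.
#' @examples
#' h <- canonical_hrf(fs = 10, duration_s = 13)
#' length(h)  # 130
#' which.max(h) / 10  # peak near 5 s
#' @export
canonical_hrf <- function(fs, duration_s, peak_shape = 6,
                          undershoot_shape = 16, undershoot_ratio = 1 / 6) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      !is.finite(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be a single positive number.")
  }
  n <- round(duration_s * fs)
  if (n < 1) abort("`duration_s * fs` must cover at least one sample.")
  kern <- function(t) {
    dgamma(t, shape = peak_shape, rate = 1) -
      undershoot_ratio * dgamma(t, shape = undershoot_shape, rate = 1)
  }
  # Normalize by the continuous-time maximum so different sampling rates
  # sample the same unit-peak function.
  peak <- optimize(kern, c(0, max(duration_s, 30)), maximum = TRUE)$objective
  t <- (seq_len(n) - 1) / fs
  kern(t) / peak
}
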