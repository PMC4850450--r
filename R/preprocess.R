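#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel of a recording with a Butterworth band-pass
#' (default 0.01-0.3 Hz, the conventional fNIRS band that removes drift,
#' respiration and cardiac pulsation while keeping the hemodynamic response),
#' applied forward and backward (`signal::filtfilt`) so the phase is zero and
#' marker timing is preserved.
#'
#' @param recording A `nirs_recording`.
#' @param low,high Band edges in Hz; requires `0 < low < high < fs / 2`.
#' @param order Total band-pass filter order (default 4, i.e. 2 poles per
#'   band edge). The effective magnitude response is squared by the
#'   forward-backward pass.
#' @return The recording with filtered `data`; markers and metadata unchanged.
#' @export
nirs_bandpass <- function(recording, low = 0.01, high = 0.3, order = 4) {
  stopifnot(inherits(recording, "nirs_recording"))
  fs <- recording$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort(sprintf(
      "Invalid band edges: need 0 < low < high < fs/2 (got %g, %g at fs = %g).",
      low, high, fs))
  }
  if (order < 2 || order %% 2 != 0) {
    abort("`order` must be an even integer >= 2.")
  }
  n <- ncol(recording$data)
  if (n < 12 * order) {
    abort("Recording too short for the filter's warm-up length.")
  }
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  out <- recording
  out$data <- t(apply(recording$data, 1, function(x) {
    signal::filtfilt(bf, x)
  }))
  rownames(out$data) <- recording$channels
  out
}

# Frequency response magnitude of the band-pass as applied (zero-phase, so
# the single-pass magnitude squared). Used to verify the filter contract.
bandpass_gain <- function(freq, fs, low = 0.01, high = 0.3, order = 4) {
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * freq / fs)
  evalp <- function(coef, z) {
    out <- 0 + 0i
    for (c in coef) out <- out * z + c
    out
  }
  h <- evalp(bf$b, z) / evalp(bf$a, z)
  Mod(h)^2
}

#' Segment a recording into peri-stimulus epochs
#'
#' Cuts one epoch per marker of the requested case: `pre_s` seconds before
#' the marker onset and `post_s` seconds from the onset on (13-s runs with
#' the defaults of a 2-s pre-stimulus baseline and an 11-s post-stimulus and
#' recovery period). The sample at position `pre_s * fs + 1` of each epoch is
#' the marker onset. Markers too close to a recording boundary for a full
#' window are dropped with a warning.
#'
#' @param recording A `nirs_recording`.
#' @param case Case label to extract (see [case_labels()]).
#' @param pre_s,post_s Epoch extent in seconds before / from the onset.
#' @return A `nirs_epochs` object: `epochs` is a trials x channels x samples
#'   array; `averaged` is filled by [normalize_and_average()].
#' @export
segment <- function(recording, case, pre_s = 2, post_s = 11) {
  stopifnot(inherits(recording, "nirs_recording"))
  onsets <- recording$markers$onset[recording$markers$case == case]
  if (length(onsets) == 0) {
    abort(sprintf("Recording %s has no markers of case '%s'.",
                  recording$subject_id, case))
  }
  fs <- recording$fs
  pre_n <- round(pre_s * fs)
  post_n <- round(post_s * fs)
  n_samp <- ncol(recording$data)
  ok <- (onsets - pre_n) >= 1 & (onsets + post_n - 1) <= n_samp
  if (any(!ok)) {
    warn(sprintf("Dropped %d trial(s) of case '%s' too close to a recording boundary (subject %s).",
                 sum(!ok), case, recording$subject_id))
  }
  onsets <- onsets[ok]
  if (length(onsets) == 0) {
    abort(sprintf("No usable trials of case '%s' for subject %s.",
                  case, recording$subject_id))
  }
  len <- pre_n + post_n
  ep <- array(NA_real_,
              dim = c(length(onsets), nrow(recording$data), len),
              dimnames = list(NULL, recording$channels, NULL))
  for (k in seq_along(onsets)) {
    ep[k, , ] <- recording$data[, (onsets[k] - pre_n):(onsets[k] + post_n - 1)]
  }
  structure(list(subject_id = recording$subject_id, group = recording$group,
                 case = case, epochs = ep, fs = fs, pre_samples = pre_n,
                 averaged = NULL, normalized = FALSE),
            class = "nirs_epochs")
}

#' @export
print.nirs_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<nirs_epochs> subject %s (%s), case '%s': %d trials x %d channels x %d samples%s\n",
              x$subject_id, x$group, x$case, d[1], d[2], d[3],
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize epochs and compute the run average
#'
#' Per trial and channel, subtracts the pre-stimulus baseline mean and (with
#' `method = "baseline_sd"`, the default) scales to unit pre-stimulus
#' standard deviation; channels whose baseline SD is zero are left unscaled.
#' The run average (`averaged`, channels x samples) is the trial mean of the
#' normalized epochs.
#'
#' @param epochs A `nirs_epochs` object from [segment()].
#' @param method `"baseline_sd"` (baseline subtraction + SD scaling) or
#'   `"baseline"` (subtraction only).
#' @return The epoch set with normalized `epochs` and `averaged` populated.
#' @export
normalize_and_average <- function(epochs, method = c("baseline_sd", "baseline")) {
  stopifnot(inherits(epochs, "nirs_epochs"))
  method <- match.arg(method)
  d <- dim(epochs$epochs)
  if (d[1] < 1) abort("Epoch set is empty.")
  pre <- seq_len(epochs$pre_samples)
  ep <- epochs$epochs
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- ep[tr, ch, ]
      x <- x - mean(x[pre])
      if (method == "baseline_sd") {
        s <- sd(ep[tr, ch, pre])
        if (s > 0) x <- x / s
      }
      ep[tr, ch, ] <- x
    }
  }
  out <- epochs
  out$epochs <- ep
  out$normalized <- TRUE
  out$norm_method <- method
  avg <- apply(ep, c(2, 3), mean)
  rownames(avg) <- dimnames(ep)[[2]]
  out$averaged <- avg
  out
}
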