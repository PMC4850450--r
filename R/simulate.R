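#' Simulation configuration for synthetic fNIRS cohorts
#'
#' Bundles every knob of the synthetic-data generator. The generator emulates
#' a block-design deception experiment recorded with a 24-channel continuous
#' wave fNIRS montage over the bilateral frontal cortex: oxyhemoglobin (HbO2)
#' traces at 10 Hz with event markers for the six trial types
#' (win-win / lose-win / lose-lose under spontaneous or instructed behavior),
#' an HRF-shaped evoked response, slow spatially structured hemodynamic
#' background activity, global physiological oscillations (Mayer waves,
#' respiration, cardiac pulsation) and white measurement noise.
#'
#' Channels are placed on two rectangular optode patches (one per entry of
#' `community_partition`, mimicking bilateral 4 x 3 sub-arrays of a frontal
#' probe pad). The structured background of channel i is a weighted sum of
#' smooth latent source signals located at every channel site, with weights
#' decaying as `exp(-d / spatial_decay)` in inter-channel distance d (grid
#' units of one inter-optode spacing). After row normalization this yields a
#' smooth spatial correlation profile: neighboring channels are strongly
#' correlated, channels on opposite patches weakly. The group coupling scales
#' how much of each channel's variance is this shared structured signal, so
#' higher coupling means uniformly stronger inter-channel correlations —
#' the generative encoding of one behavioral group forming closer, denser
#' functional networks than the other.
#'
#' @param n_subjects Subjects per behavioral group (default 24).
#' @param n_channels Number of fNIRS channels / network nodes (default 24).
#' @param fs Sampling rate in Hz (default 10).
#' @param n_trials_per_case Trials (markers) per case label (default 10).
#' @param epoch_pre_s,epoch_post_s Pre-stimulus and post-stimulus epoch
#'   lengths in seconds (defaults 2 and 11: 13-s runs).
#' @param group_coupling Named numeric in \[0, 1\]: base coupling (standard
#'   deviation share of the shared structured signal) per group. Names define
#'   the group labels; the first group is conventionally the stronger-coupled
#'   ("spontaneous") one.
#' @param community_partition Integer vector, one entry per channel, assigning
#'   channels to spatial patches. Default: two patches of equal size.
#' @param spatial_decay Length scale (in inter-optode spacings) of the
#'   exponential decay of latent-source loadings; `Inf` makes all channels
#'   load identically (perfect coupling structure).
#' @param loading_jitter Half-width of the uniform per-channel, per-subject
#'   multiplicative jitter on coupling strength (default 0.12), creating
#'   channel and subject heterogeneity in correlation strength.
#' @param noise_bands List of `c(freq, amp)` pairs: sinusoidal physiological
#'   oscillators shared across channels (systemic physiology). Defaults:
#'   0.1 Hz Mayer waves, 0.3 Hz respiration, 1 Hz cardiac.
#' @param white_noise_sd Standard deviation of channel-independent white
#'   measurement noise, relative to the unit-variance background.
#' @param evoked_amplitude Peak amplitude of the HRF-shaped evoked response
#'   relative to the unit-variance background.
#' @param trial_spacing_s,spacing_jitter_s Mean inter-trial onset spacing and
#'   its uniform jitter half-width, in seconds.
#' @param patch_gap Extra distance (grid units) separating the two patches.
#' @param background_smooth_s Gaussian smoothing width (seconds) of the slow
#'   background signals; sets their decorrelation time and hence the number
#'   of effective samples per epoch.
#' @param signal_scale Overall output scale in mM·mm (HbO2 concentration
#'   change times path length); affects units only, not correlations.
#' @param seed Master RNG seed; per-subject seeds are derived from it (see
#'   [simulate_recording()]).
#' @return A `nirs_sim_config` list.
#' @seealso [simulate_recording()], [simulate_cohort()]
#' @export
sim_config <- function(n_subjects = 24,
                       n_channels = 24,
                       fs = 10,
                       n_trials_per_case = 10,
                       epoch_pre_s = 2,
                       epoch_post_s = 11,
                       group_coupling = c(spontaneous = 0.97, control = 0.90),
                       community_partition = NULL,
                       spatial_decay = 3.0,
                       loading_jitter = 0.12,
                       noise_bands = list(mayer = c(0.1, 0.25),
                                          respiration = c(0.3, 0.2),
                                          cardiac = c(1.0, 0.15)),
                       white_noise_sd = 0.25,
                       evoked_amplitude = 0.2,
                       trial_spacing_s = 17,
                       spacing_jitter_s = 2,
                       patch_gap = 3,
                       background_smooth_s = 0.5,
                       signal_scale = 0.05,
                       seed = 1L) {
  if (is.null(community_partition)) {
    community_partition <- rep(1:2, length.out = n_channels)
    community_partition <- sort(community_partition)
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_channels = as.integer(n_channels),
    fs = fs,
    n_trials_per_case = as.integer(n_trials_per_case),
    epoch_pre_s = epoch_pre_s,
    epoch_post_s = epoch_post_s,
    group_coupling = group_coupling,
    community_partition = as.integer(community_partition),
    spatial_decay = spatial_decay,
    loading_jitter = loading_jitter,
    noise_bands = noise_bands,
    white_noise_sd = white_noise_sd,
    evoked_amplitude = evoked_amplitude,
    trial_spacing_s = trial_spacing_s,
    spacing_jitter_s = spacing_jitter_s,
    patch_gap = patch_gap,
    background_smooth_s = background_smooth_s,
    signal_scale = signal_scale,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "nirs_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_channels < 2) abort("`n_channels` must be at least 2.")
  if (cfg$n_subjects < 1) abort("`n_subjects` must be at least 1.")
  if (!is.finite(cfg$fs) || cfg$fs <= 0) abort("`fs` must be positive.")
  if (is.null(names(cfg$group_coupling)) ||
      any(!nzchar(names(cfg$group_coupling)))) {
    abort("`group_coupling` must be a named numeric vector of group labels.")
  }
  if (any(cfg$group_coupling < 0 | cfg$group_coupling > 1)) {
    abort("`group_coupling` values must lie in [0, 1].")
  }
  if (length(cfg$community_partition) != cfg$n_channels) {
    abort("`community_partition` must have one entry per channel.")
  }
  n_epoch <- (cfg$epoch_pre_s + cfg$epoch_post_s) * cfg$fs
  if (abs(n_epoch - round(n_epoch)) > 1e-8) {
    abort("(epoch_pre_s + epoch_post_s) * fs must be an integer sample count.")
  }
  if (cfg$n_trials_per_case < 1) abort("`n_trials_per_case` must be >= 1.")
  if (cfg$white_noise_sd < 0) abort("`white_noise_sd` must be >= 0.")
  if (cfg$loading_jitter < 0 || cfg$loading_jitter >= 1) {
    abort("`loading_jitter` must lie in [0, 1).")
  }
  invisible(cfg)
}

#' Trial-type labels of the deception task
#'
#' The three outcome/answer combinations of the card-game deception task.
#' Each occurs once under spontaneous behavior (cases 1-3, the subject
#' chooses freely) and once under instructed control behavior (cases 4-6).
#' @return Character vector of the three case labels.
#' @export
case_labels <- function() c("win-win", "lose-win", "lose-lose")

#' @export
print.nirs_sim_config <- function(x, ...) {
  cat("<nirs_sim_config>\n")
  cat(sprintf("  %d subjects/group x %d channels @ %g Hz\n",
              x$n_subjects, x$n_channels, x$fs))
  cat(sprintf("  groups: %s (coupling %s)\n",
              paste(names(x$group_coupling), collapse = ", "),
              paste(format(x$group_coupling), collapse = ", ")))
  cat(sprintf("  %d trials/case, epochs %g+%g s, seed %d\n",
              x$n_trials_per_case, x$epoch_pre_s, x$epoch_post_s, x$seed))
  invisible(x)
}

# Channel site coordinates: one near-square grid per patch, patches laid out
# along x and separated by `patch_gap` extra spacing. Unit = one inter-optode
# spacing.
channel_positions <- function(partition, patch_gap = 3) {
  comms <- sort(unique(partition))
  pos <- matrix(0, length(partition), 2,
                dimnames = list(NULL, c("x", "y")))
  x_off <- 0
  for (k in comms) {
    idx <- which(partition == k)
    nc <- length(idx)
    n_col <- ceiling(sqrt(nc))
    n_row <- ceiling(nc / n_col)
    gx <- (seq_along(idx) - 1) %% n_col
    gy <- (seq_along(idx) - 1) %/% n_col
    pos[idx, 1] <- x_off + gx
    pos[idx, 2] <- gy
    x_off <- x_off + n_col - 1 + patch_gap
  }
  pos
}

# Unit-variance smooth (band-limited) Gaussian noise: white noise circularly
# convolved with a Gaussian kernel of width smooth_s seconds, kernel scaled to
# unit l2 norm so the output variance stays 1.
smooth_noise <- function(n, fs, smooth_s = 1.2) {
  half <- max(1L, ceiling(3 * smooth_s * fs))
  k <- exp(-0.5 * ((-half:half) / (smooth_s * fs))^2)
  k <- k / sqrt(sum(k^2))
  x <- rnorm(n + 2L * half)
  y <- stats::filter(x, k, method = "convolution", sides = 2)
  as.numeric(y[(half + 1L):(half + n)])
}

# Deterministic per-subject seed splitting: mixes the master seed with hashes
# of the subject id and group label, modulo 2^31 - 1.
derive_subject_seed <- function(master, subject_id, group) {
  id_chars <- utf8ToInt(as.character(subject_id))
  id_hash <- sum(id_chars * seq_along(id_chars))
  grp_hash <- sum(utf8ToInt(as.character(group)))
  as.integer((as.double(master) * 2654435 + id_hash * 104729 +
                grp_hash * 7919) %% 2147483647)
}

#' Simulate one synthetic fNIRS recording
#'
#' Generates a continuous multichannel HbO2 recording for one subject in one
#' behavioral group, with `n_trials_per_case` markers for each of the three
#' case labels, randomly interleaved. Channel signals are the sum of
#' (i) a spatially structured smooth background whose inter-channel
#' correlation is controlled by the group coupling, (ii) an HRF-convolved
#' evoked response at the trial onsets, (iii) global sinusoidal physiological
#' oscillations and (iv) white measurement noise. See [sim_config()] for the
#' generative model.
#'
#' The RNG seed is derived deterministically from the configuration's master
#' seed, the subject id and the group label, so any subject can be
#' regenerated in isolation and a full cohort is reproducible.
#'
#' @param config A [sim_config()] object.
#' @param subject_id Subject identifier (used in the seed derivation).
#' @param group Group label; must be a name of `config$group_coupling`.
#' @param seed Optional explicit seed overriding the derived one.
#' @return A `nirs_recording`: list with `subject_id`, `group`, `channels`,
#'   `data` (channels x samples matrix, mM·mm), `fs` and `markers` (tibble
#'   with 1-based `onset` sample and `case` label).
#' @export
simulate_recording <- function(config, subject_id, group, seed = NULL) {
  validate_sim_config(config)
  if (!group %in% names(config$group_coupling)) {
    abort(sprintf("Unknown group label '%s'; expected one of: %s.", group,
                  paste(names(config$group_coupling), collapse = ", ")))
  }
  if (is.null(seed)) {
    seed <- derive_subject_seed(config$seed, subject_id, group)
  }
  fs <- config$fs
  nc <- config$n_channels
  pre_n <- round(config$epoch_pre_s * fs)
  post_n <- round(config$epoch_post_s * fs)

  withr::with_seed(seed, {
    # --- trial schedule -----------------------------------------------------
    cases <- sample(rep(case_labels(), config$n_trials_per_case))
    n_trials <- length(cases)
    jit <- runif(n_trials, -config$spacing_jitter_s, config$spacing_jitter_s)
    onset_s <- 5 + config$epoch_pre_s +
      (seq_len(n_trials) - 1) * config$trial_spacing_s + jit
    onsets <- round(onset_s * fs) + 1L
    n_samples <- max(onsets) + post_n + round(5 * fs)

    # --- structured background ---------------------------------------------
    pos <- channel_positions(config$community_partition, config$patch_gap)
    d <- as.matrix(stats::dist(pos))
    w <- if (is.infinite(config$spatial_decay)) {
      matrix(1, nc, nc)
    } else {
      exp(-d / config$spatial_decay)
    }
    w <- w / sqrt(rowSums(w^2))
    u <- runif(nc, 1 - config$loading_jitter, 1 + config$loading_jitter)
    a <- pmin(config$group_coupling[[group]] * u, 1)
    sm <- config$background_smooth_s
    sources <- t(vapply(seq_len(nc),
                        function(i) smooth_noise(n_samples, fs, sm),
                        numeric(n_samples)))
    structured <- w %*% sources
    idio <- t(vapply(seq_len(nc),
                     function(i) smooth_noise(n_samples, fs, sm),
                     numeric(n_samples)))
    background <- a * structured + sqrt(pmax(0, 1 - a^2)) * idio

    # --- evoked response (shared across channels) ---------------------------
    stick <- numeric(n_samples)
    stick[onsets] <- 1
    hrf <- canonical_hrf(fs, duration_s = 25)
    ev <- stats::convolve(stick, rev(hrf), type = "open")[seq_len(n_samples)]
    evoked <- config$evoked_amplitude * ev

    # --- physiological oscillations (channel-specific phase lags) -----------
    tt <- (seq_len(n_samples) - 1) / fs
    phys <- matrix(0, nc, n_samples)
    for (b in config$noise_bands) {
      phase <- runif(nc, 0, 2 * pi)
      phys <- phys + b[[2]] *
        sin(outer(phase, 2 * pi * b[[1]] * tt, `+`))
    }

    noise <- config$white_noise_sd *
      matrix(rnorm(nc * n_samples), nc, n_samples)
    data <- config$signal_scale *
      (background + matrix(evoked, nc, n_samples, byrow = TRUE) +
         phys + noise)
  })

  channels <- sprintf("CH%02d", seq_len(nc))
  rownames(data) <- channels
  new_recording(subject_id = as.character(subject_id), group = group,
                channels = channels, data = data, fs = fs,
                markers = tibble::tibble(onset = onsets, case = cases))
}

new_recording <- function(subject_id, group, channels, data, fs, markers) {
  stopifnot(nrow(data) == length(channels))
  structure(list(subject_id = subject_id, group = group, channels = channels,
                 data = data, fs = fs, markers = markers),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording> subject %s (%s): %d channels x %d samples @ %g Hz, %d markers\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
              nrow(x$markers)))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.nirs_recording <- function(x, ...) {
  tibble::tibble(
    subject = x$subject_id,
    group = x$group,
    channel = rep(x$channels, each = ncol(x$data)),
    sample = rep(seq_len(ncol(x$data)), times = nrow(x$data)),
    value = as.numeric(t(x$data))
  )
}

#' Simulate a two-group synthetic cohort
#'
#' Generates `n_subjects` recordings for every group in
#' `config$group_coupling` (the same subject ids appear in both groups,
#' mirroring a within-subject task design analyzed between conditions).
#' Per-subject seeds are derived from the master seed, so the cohort is fully
#' reproducible and individual recordings can be regenerated independently.
#'
#' @param config A [sim_config()] object.
#' @return A `nirs_cohort`: list of `nirs_recording` objects.
#' @examples
#' cfg <- sim_config(n_subjects = 2, n_trials_per_case = 3, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' length(cohort)  # 4 recordings: 2 subjects x 2 groups
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  recs <- list()
  for (group in names(config$group_coupling)) {
    for (s in seq_len(config$n_subjects)) {
      id <- sprintf("S%02d", s)
      recs[[length(recs) + 1L]] <- simulate_recording(config, id, group)
    }
  }
  structure(recs, class = "nirs_cohort")
}

#' @export
print.nirs_cohort <- function(x, ...) {
  groups <- table(vapply(x, function(r) r$group, character(1)))
  cat(sprintf("<nirs_cohort> %d recordings (%s)\n", length(x),
              paste(sprintf("%s: %d", names(groups), groups), collapse = ", ")))
  invisible(x)
}
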