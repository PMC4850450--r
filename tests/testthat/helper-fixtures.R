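# Hand-built containers for unit tests.

make_recording <- function(data, fs = 10, markers = NULL,
                           subject_id = "T01", group = "spontaneous") {
  if (is.null(markers)) markers <- tibble::tibble(onset = integer(),
                                                  case = character())
  channels <- sprintf("CH%02d", seq_len(nrow(data)))
  rownames(data) <- channels
  nirsnet:::new_recording(subject_id = subject_id, group = group,
                          channels = channels, data = data, fs = fs,
                          markers = markers)
}

# Wrap a channels x samples matrix as a single-trial, already-normalized
# epoch set so pearson_matrix() uses the values as-is.
epochs_from_matrix <- function(x, fs = 10, pre_samples = 20) {
  ep <- array(0, dim = c(1, nrow(x), ncol(x)),
              dimnames = list(NULL, sprintf("CH%02d", seq_len(nrow(x))), NULL))
  ep[1, , ] <- x
  structure(list(subject_id = "T01", group = "spontaneous", case = "win-win",
                 epochs = ep, fs = fs, pre_samples = pre_samples,
                 averaged = x, normalized = TRUE),
            class = "nirs_epochs")
}

# Small cohort configuration kept light for unit tests.
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_subjects = 2, n_trials_per_case = 3,
                                 seed = 7), list(...))
  do.call(sim_config, args)
}

metric_table <- function(values, group, threshold = c(0.3, 0.4),
                         case = "win-win") {
  # one row per subject x threshold with identical values per threshold
  purrr::map(seq_along(threshold), function(i) {
    tibble::tibble(subject_id = sprintf("S%02d", seq_along(values)),
                   group = group, case = case, threshold = threshold[i],
                   C = values, L = values + 1, K_mean = values * 2,
                   sigma = values + 0.5, connected = TRUE)
  }) |> purrr::list_rbind()
}

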