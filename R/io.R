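#' Write and read cohorts as long-format text files
#'
#' `write_recordings()` stores a cohort as two tab-separated files in `dir`:
#' `series.tsv` with one row per (subject, group, channel, sample) and
#' `markers.tsv` with one row per trial marker. `read_recordings()` inverts
#' it, validating the schema: sample indices must be a complete 1..n sequence
#' per channel, case labels must be known, and markers whose epoch window
#' would fall outside the recording are rejected with a warning.
#'
#' @param recordings A `nirs_cohort` or list of `nirs_recording` objects.
#' @param dir Directory (created if needed).
#' @param fs Sampling rate to assume when reading (written files carry no
#'   header metadata; default 10 Hz).
#' @return `write_recordings()` returns `dir` invisibly; `read_recordings()`
#'   a `nirs_cohort`.
#' @export
write_recordings <- function(recordings, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  series <- purrr::map(recordings, as_tibble) |> purrr::list_rbind()
  markers <- purrr::map(recordings, function(r) {
    dplyr::mutate(r$markers, subject = r$subject_id, group = r$group,
                  .before = 1)
  }) |> purrr::list_rbind()
  readr::write_tsv(series, file.path(dir, "series.tsv"))
  readr::write_tsv(markers, file.path(dir, "markers.tsv"))
  invisible(dir)
}

#' @rdname write_recordings
#' @param epoch_pre_s,epoch_post_s Epoch window used to validate markers.
#' @export
read_recordings <- function(dir, fs = 10, epoch_pre_s = 2, epoch_post_s = 11) {
  series_path <- file.path(dir, "series.tsv")
  markers_path <- file.path(dir, "markers.tsv")
  for (p in c(series_path, markers_path)) {
    if (!file.exists(p)) abort(sprintf("Missing input file: %s", p))
  }
  series <- readr::read_tsv(series_path, show_col_types = FALSE)
  markers <- readr::read_tsv(markers_path, show_col_types = FALSE)
  needed <- c("subject", "group", "channel", "sample", "value")
  if (!all(needed %in% names(series))) {
    abort(sprintf("series.tsv must have columns: %s.",
                  paste(needed, collapse = ", ")))
  }
  bad_case <- which(!markers$case %in% case_labels())
  if (length(bad_case) > 0) {
    abort(sprintf("markers.tsv has unknown case labels at row(s): %s.",
                  paste(utils::head(bad_case, 5), collapse = ", ")))
  }
  pre_n <- round(epoch_pre_s * fs)
  post_n <- round(epoch_post_s * fs)
  keys <- dplyr::distinct(series, .data$subject, .data$group)
  recs <- purrr::pmap(keys, function(subject, group) {
    sub <- dplyr::filter(series, .data$subject == !!subject,
                         .data$group == !!group)
    chans <- unique(sub$channel)
    n <- max(sub$sample)
    data <- matrix(NA_real_, length(chans), n,
                   dimnames = list(chans, NULL))
    for (ch in chans) {
      rows <- sub[sub$channel == ch, ]
      if (is.unsorted(rows$sample, strictly = TRUE) ||
          nrow(rows) != n || rows$sample[1] != 1) {
        abort(sprintf(
          "Non-monotone or incomplete sample indices for subject %s channel %s.",
          subject, ch))
      }
      data[ch, ] <- rows$value
    }
    mk <- dplyr::filter(markers, .data$subject == !!subject,
                        .data$group == !!group)
    ok <- (mk$onset - pre_n) >= 1 & (mk$onset + post_n - 1) <= n
    if (any(!ok)) {
      warn(sprintf("Rejected %d marker(s) outside recording bounds (subject %s, %s).",
                   sum(!ok), subject, group))
      mk <- mk[ok, ]
    }
    new_recording(subject_id = subject, group = group, channels = chans,
                  data = data, fs = fs,
                  markers = tibble::tibble(onset = mk$onset, case = mk$case))
  })
  structure(recs, class = "nirs_cohort")
}

#' Write a correlation matrix or binary network as labeled TSV
#'
#' Square tab-separated layout: a header of node labels and one label column,
#' so the file is self-describing. `read_matrix()` inverts it (bit-exactly
#' for binary adjacency, to full double precision for correlations).
#'
#' @param x A `nirs_corrmat` or `nirs_network`.
#' @param path Output file.
#' @return `path`, invisibly; `read_matrix()` returns a labeled base matrix.
#' @export
write_matrix <- function(x, path) {
  m <- if (inherits(x, "nirs_corrmat")) x$values
       else if (inherits(x, "nirs_network")) x$adjacency
       else as.matrix(x)
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  names(df) <- colnames(m)
  df <- dplyr::bind_cols(tibble::tibble(node = rownames(m)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1])
  dimnames(m) <- list(labels, colnames(m))
  m
}

#' Export a network for BrainNet Viewer
#'
#' Writes the standard BrainNet Viewer text pair: `<stem>.node` with one row
#' per node (`x y z color size label`, MNI coordinates) and `<stem>.edge`
#' with the full N x N adjacency matrix.
#'
#' @param net A `nirs_network`.
#' @param coords Data frame with one row per node and columns `x`, `y`, `z`;
#'   optional `label` (default: node labels), `color` (default 1) and `size`
#'   (default: node degree, or 1 for isolated nodes).
#' @param path_stem Output path without extension.
#' @return Character vector of the two file paths, invisibly.
#' @export
export_brainnet <- function(net, coords, path_stem) {
  stopifnot(inherits(net, "nirs_network"))
  coords <- as.data.frame(coords)
  if (nrow(coords) != length(net$labels)) {
    abort(sprintf("Coordinate table has %d rows for %d nodes.",
                  nrow(coords), length(net$labels)))
  }
  if (!all(c("x", "y", "z") %in% names(coords))) {
    abort("`coords` must have columns x, y, z.")
  }
  deg <- rowSums(net$adjacency)
  node <- data.frame(
    x = coords$x, y = coords$y, z = coords$z,
    color = if ("color" %in% names(coords)) coords$color else 1,
    size = if ("size" %in% names(coords)) coords$size else pmax(deg, 1),
    label = if ("label" %in% names(coords)) coords$label else net$labels
  )
  node_path <- paste0(path_stem, ".node")
  edge_path <- paste0(path_stem, ".edge")
  utils::write.table(node, node_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(net$adjacency, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Packaged example channel layout
#'
#' A synthetic 24-channel example layout of MNI-like coordinates over the
#' bilateral dorsolateral frontal cortex (two 4 x 3 patches), for use with
#' [export_brainnet()] when no digitized coordinates are available. The
#' coordinates are illustrative, not registered measurements.
#'
#' @return Tibble with columns `label`, `x`, `y`, `z`.
#' @export
example_channel_layout <- function() {
  path <- system.file("extdata", "channel_layout_24_synthetic.tsv",
                      package = "nirsnet")
  readr::read_tsv(path, show_col_types = FALSE)
}
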