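#' Channel-by-channel Pearson correlation matrix
#'
#' Builds the functional-connectivity matrix of an epoch set: nodes are fNIRS
#' channels, entry (i, j) is the sample Pearson correlation between the
#' analysis time series of channels i and j. By default the analysis series
#' is the per-trial normalized epochs concatenated across trials of the case;
#' `series = "averaged"` uses the run-averaged epoch instead.
#'
#' Channels with zero variance get 0 on all their off-diagonal entries (with
#' a warning) rather than `NaN`; the diagonal is exactly 1.
#'
#' @param epochs A normalized `nirs_epochs` (see [normalize_and_average()]).
#'   Un-normalized epochs are normalized first with the default method.
#' @param series `"concatenated"` (default) or `"averaged"`.
#' @return A `nirs_corrmat`: list with `labels`, `values` (symmetric N x N,
#'   unit diagonal), `n_samples_used`, `subject_id`, `case`, `group`.
#' @export
pearson_matrix <- function(epochs, series = c("concatenated", "averaged")) {
  stopifnot(inherits(epochs, "nirs_epochs"))
  series <- match.arg(series)
  if (!isTRUE(epochs$normalized)) {
    epochs <- normalize_and_average(epochs)
  }
  d <- dim(epochs$epochs)
  x <- switch(series,
    concatenated = {
      # channels x (trials * samples)
      m <- matrix(aperm(epochs$epochs, c(2, 3, 1)), nrow = d[2])
      m
    },
    averaged = epochs$averaged
  )
  if (ncol(x) < 3) abort("Need at least 3 time samples for correlations.")
  if (nrow(x) < 2) abort("Need at least 2 channels.")
  sds <- apply(x, 1, sd)
  vals <- suppressWarnings(cor(t(x)))
  if (any(sds == 0)) {
    warn(sprintf("%d zero-variance channel(s); their correlations set to 0.",
                 sum(sds == 0)))
    vals[sds == 0, ] <- 0
    vals[, sds == 0] <- 0
  }
  vals[!is.finite(vals)] <- 0
  vals <- pmin(pmax(vals, -1), 1)
  diag(vals) <- 1
  labels <- dimnames(epochs$epochs)[[2]]
  if (is.null(labels)) labels <- sprintf("CH%02d", seq_len(nrow(x)))
  dimnames(vals) <- list(labels, labels)
  new_corrmat(labels = labels, values = vals, n_samples_used = ncol(x),
              subject_id = epochs$subject_id, case = epochs$case,
              group = epochs$group)
}

new_corrmat <- function(labels, values, n_samples_used, subject_id,
                        case = NA_character_, group = NA_character_) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            nrow(values) == length(labels))
  if (max(abs(values - t(values))) > 1e-12) {
    abort("Correlation matrix must be symmetric.")
  }
  structure(list(labels = labels, values = values,
                 n_samples_used = n_samples_used, subject_id = subject_id,
                 case = case, group = group),
            class = "nirs_corrmat")
}

#' Construct a correlation matrix object from a plain matrix
#'
#' @param values Symmetric numeric matrix with entries in \[-1, 1\].
#' @param labels Node labels; defaults to row names or `CH01`, `CH02`, ...
#' @param n_samples_used Number of time samples behind the correlations
#'   (needed by [check_bounds()]); `NA` if unknown.
#' @param subject_id,case,group Optional metadata.
#' @return A `nirs_corrmat`.
#' @export
as_corrmat <- function(values, labels = NULL, n_samples_used = NA_integer_,
                       subject_id = "matrix", case = NA_character_,
                       group = NA_character_) {
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- sprintf("CH%02d", seq_len(nrow(values)))
  }
  if (any(values < -1 - 1e-9 | values > 1 + 1e-9)) {
    abort("Correlation values must lie in [-1, 1].")
  }
  values <- pmin(pmax(values, -1), 1)
  diag(values) <- 1
  dimnames(values) <- list(labels, labels)
  new_corrmat(labels, values, n_samples_used, subject_id, case, group)
}

#' @export
print.nirs_corrmat <- function(x, ...) {
  cat(sprintf("<nirs_corrmat> %s%s: %d x %d, n = %s samples\n",
              x$subject_id,
              if (!is.na(x$case)) paste0(" (", x$case, ")") else "",
              nrow(x$values), ncol(x$values), format(x$n_samples_used)))
  invisible(x)
}

#' @export
as_tibble.nirs_corrmat <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    row = rep(x$labels, times = length(x$labels)),
    col = rep(x$labels, each = length(x$labels)),
    r = as.numeric(v)
  )
}

#' Average correlation matrices across subjects
#'
#' Element-wise arithmetic mean of correlation matrices sharing one label
#' order — the group-average connectivity matrix behind group-level network
#' figures. Optionally averages on the Fisher-z scale
#' (`tanh(mean(atanh(r)))`) instead of the raw coefficients.
#'
#' @param matrices List of `nirs_corrmat` objects with identical labels.
#' @param fisher_z Average on the variance-stabilized z scale (default
#'   `FALSE`: plain arithmetic mean of the coefficients).
#' @return A `nirs_corrmat` with `subject_id = "group-average"`.
#' @export
group_average <- function(matrices, fisher_z = FALSE) {
  if (length(matrices) == 0) abort("Need at least one matrix.")
  stopifnot(all(vapply(matrices, inherits, logical(1), "nirs_corrmat")))
  labels <- matrices[[1]]$labels
  for (m in matrices) {
    if (!identical(m$labels, labels)) {
      abort("All matrices must share the same channel labels in the same order.")
    }
  }
  arr <- vapply(matrices, function(m) m$values,
                matrix(0, length(labels), length(labels)))
  avg <- if (fisher_z) {
    z <- atanh(pmin(pmax(arr, -1 + 1e-12), 1 - 1e-12))
    tanh(apply(z, c(1, 2), mean))
  } else {
    apply(arr, c(1, 2), mean)
  }
  diag(avg) <- 1
  dimnames(avg) <- list(labels, labels)
  grp <- unique(vapply(matrices, function(m) m$group, character(1)))
  cs <- unique(vapply(matrices, function(m) m$case, character(1)))
  new_corrmat(labels, avg,
              n_samples_used = matrices[[1]]$n_samples_used,
              subject_id = "group-average",
              case = if (length(cs) == 1) cs else NA_character_,
              group = if (length(grp) == 1) grp else NA_character_)
}
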