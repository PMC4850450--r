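#' Tidy a sweep comparison
#'
#' Returns the per-threshold, per-metric comparison in long "one group per
#' row" form: columns `threshold`, `metric`, `group`, `mean`, `sd`, `n`, with
#' the test columns (`t`, `p`, `significant`) repeated for both rows of a
#' pair.
#'
#' @param x A `nirs_sweep` from [compare_groups()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nirs_sweep <- function(x, ...) {
  g <- attr(x, "groups")
  base <- tibble::as_tibble(x)
  long_a <- dplyr::transmute(base, .data$threshold, .data$metric,
                             group = g[["a"]], mean = .data$mean_a,
                             sd = .data$sd_a, n = .data$n_a,
                             t = .data$t, p = .data$p,
                             significant = .data$significant)
  long_b <- dplyr::transmute(base, .data$threshold, .data$metric,
                             group = g[["b"]], mean = .data$mean_b,
                             sd = .data$sd_b, n = .data$n_b,
                             t = .data$t, p = .data$p,
                             significant = .data$significant)
  dplyr::arrange(dplyr::bind_rows(long_a, long_b),
                 .data$metric, .data$threshold, .data$group)
}

#' One-row summary of a sweep comparison
#'
#' @param x A `nirs_sweep` from [compare_groups()].
#' @param ... Unused.
#' @return One-row tibble: grid size, test used, and the number of
#'   significant thresholds per metric.
#' @export
glance.nirs_sweep <- function(x, ...) {
  sig <- tibble::as_tibble(x) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(n_sig = sum(.data$significant, na.rm = TRUE)) |>
    tidyr::pivot_wider(names_from = "metric", values_from = "n_sig",
                       names_prefix = "n_sig_")
  dplyr::bind_cols(
    tibble::tibble(
      n_thresholds = length(unique(x$threshold)),
      t_min = min(x$threshold), t_max = max(x$threshold),
      test = attr(x, "test"), alpha = attr(x, "alpha")
    ),
    sig
  )
}
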