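#' Plot sweep curves with group comparison
#'
#' Mean +/- SD curves of the four network indices across the threshold grid,
#' one panel per metric, one color per group, with asterisks marking
#' thresholds where the two-sample test is significant.
#'
#' @param object A `nirs_sweep` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nirs_sweep <- function(object, ...) {
  long <- tidy(object)
  ylim <- long |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(y = max(.data$mean + .data$sd, na.rm = TRUE) * 1.05)
  stars <- tibble::as_tibble(object) |>
    dplyr::filter(.data$significant) |>
    dplyr::left_join(ylim, by = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$mean,
                                     color = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_text(data = stars,
                       ggplot2::aes(x = .data$threshold, y = .data$y),
                       label = "*", inherit.aes = FALSE, size = 5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "threshold T", y = "mean ± SD",
                  color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Correlation-matrix heatmap
#'
#' @param object A `nirs_corrmat`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nirs_corrmat <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = sprintf("%s%s", object$subject_id,
                                  if (!is.na(object$case))
                                    paste0(" — ", object$case) else "")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Run-average epoch time courses
#'
#' Plots the trial-averaged normalized HbO2 response of every channel,
#' with the stimulus onset marked.
#'
#' @param object A normalized `nirs_epochs` (with `averaged` populated).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nirs_epochs <- function(object, ...) {
  if (is.null(object$averaged)) {
    abort("Run normalize_and_average() before plotting.")
  }
  avg <- object$averaged
  tt <- (seq_len(ncol(avg)) - 1 - object$pre_samples) / object$fs
  df <- tibble::tibble(
    channel = rep(rownames(avg), each = ncol(avg)),
    time = rep(tt, times = nrow(avg)),
    value = as.numeric(t(avg))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from onset (s)", y = "normalized HbO2",
                  title = sprintf("subject %s — %s", object$subject_id,
                                  object$case)) +
    ggplot2::theme_minimal()
}
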