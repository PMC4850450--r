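#' Threshold grid for the network sweep
#'
#' Inclusive arithmetic grid of binarization thresholds. The default,
#' 0.275 to 0.625 in steps of 0.025 (15 values), spans the range where
#' correlations are individually significant at the bottom and the networks
#' remain node-connected at the top.
#'
#' @param t_min,t_max Grid end points (both included), `t_min <= t_max`.
#' @param step Positive step size.
#' @return Numeric vector of thresholds.
#' @export
threshold_grid <- function(t_min = 0.275, t_max = 0.625, step = 0.025) {
  if (!(step > 0)) abort("`step` must be positive.")
  if (t_min > t_max) abort("`t_min` must not exceed `t_max`.")
  n <- floor((t_max - t_min) / step + 1e-9)
  grid <- t_min + step * (0:n)
  if (length(grid) == 0) abort("Empty threshold grid.")
  grid
}

#' Diagnostic bounds for the threshold grid
#'
#' Reports (without enforcing) the usable range of a threshold grid for a
#' set of subject correlation matrices: `t_min_ok` is the smallest grid value
#' at or above the critical |r| for a two-sided test of zero correlation at
#' level `alpha` (via the exact relation \eqn{t = r \sqrt{(n-2)/(1-r^2)}}),
#' so every retained edge is individually significant; `t_max_ok` is the
#' largest grid value at which every subject network still has mean degree at
#' least `ln(N)`, the standard connectivity heuristic.
#'
#' @param matrices List of `nirs_corrmat` objects (one per subject).
#' @param n_samples Number of time samples behind each correlation; defaults
#'   to the matrices' own `n_samples_used`.
#' @param alpha Significance level for the edge test.
#' @param grid Threshold grid to scan.
#' @return One-row tibble: `t_min_ok`, `t_max_ok` (NA when no grid value
#'   qualifies), `r_crit`, `ln_n`.
#' @export
check_bounds <- function(matrices, n_samples = NULL, alpha = 0.05,
                         grid = threshold_grid()) {
  if (inherits(matrices, "nirs_corrmat")) matrices <- list(matrices)
  if (is.null(n_samples)) n_samples <- matrices[[1]]$n_samples_used
  if (!is.finite(n_samples) || n_samples < 4) {
    abort("`n_samples` must be at least 4.")
  }
  t_crit <- qt(1 - alpha / 2, df = n_samples - 2)
  r_crit <- t_crit / sqrt(n_samples - 2 + t_crit^2)
  t_min_ok <- if (any(grid >= r_crit)) min(grid[grid >= r_crit]) else NA_real_
  n_nodes <- length(matrices[[1]]$labels)
  ln_n <- log(n_nodes)
  conn_ok <- vapply(grid, function(T) {
    all(vapply(matrices, function(m) {
      average_degree(binarize(m, T)) >= ln_n
    }, logical(1)))
  }, logical(1))
  t_max_ok <- if (any(conn_ok)) max(grid[conn_ok]) else NA_real_
  tibble::tibble(t_min_ok = t_min_ok, t_max_ok = t_max_ok,
                 r_crit = r_crit, ln_n = ln_n)
}

#' Per-subject network metrics across the threshold sweep
#'
#' Runs the full single-subject pipeline for every recording: band-pass
#' filter, segment the requested case, normalize and average, Pearson
#' correlation matrix, then for each threshold binarize and compute C, L,
#' K_mean plus the degree-preserving null reference and sigma. Subjects with
#' no usable trials are dropped with a warning. The whole computation runs
#' under a single local seed, so results are reproducible.
#'
#' Empty networks get `C = 0`, `K_mean = 0` and `NA` path length; networks
#' with fewer than 2 edges have no null reference and `NA` sigma.
#'
#' @param recordings A `nirs_cohort` or list of `nirs_recording` objects.
#' @param case Case label to analyze.
#' @param grid Threshold grid (default [threshold_grid()]).
#' @param null_n Random networks per null ensemble (default 100).
#' @param seed Seed for the null ensembles.
#' @param low,high Band-pass edges in Hz.
#' @param series,normalize Passed to [pearson_matrix()] and
#'   [normalize_and_average()].
#' @return Tibble with one row per subject x threshold: `subject_id`,
#'   `group`, `case`, `threshold`, `n_epochs`, `n_edges`, `C`, `L`,
#'   `K_mean`, `C_rand`, `L_rand`, `sigma`, `connected`.
#' @export
subject_metrics <- function(recordings, case, grid = threshold_grid(),
                            null_n = 100, seed = 1L, low = 0.01, high = 0.3,
                            series = "concatenated",
                            normalize = "baseline_sd") {
  stopifnot(length(recordings) >= 1)
  withr::with_seed(seed, {
    rows <- purrr::map(recordings, function(rec) {
      prep <- tryCatch({
        eps <- rec |>
          nirs_bandpass(low = low, high = high) |>
          segment(case = case) |>
          normalize_and_average(method = normalize)
        list(mat = pearson_matrix(eps, series = series),
             n_ep = dim(eps$epochs)[1])
      }, error = function(e) {
        warn(sprintf("Dropping subject %s (%s): %s",
                     rec$subject_id, rec$group, conditionMessage(e)))
        NULL
      })
      if (is.null(prep)) return(NULL)
      mat <- prep$mat
      n_ep <- prep$n_ep
      purrr::map(grid, function(T) {
        net <- binarize(mat, T)
        m <- network_metrics(net)
        if (m$n_edges >= 2) {
          null <- null_ensemble(net, n_random = null_n)
          sig <- tryCatch(
            small_worldness(m$C, m$L, null$C_rand, null$L_rand),
            error = function(e) NA_real_)
          m$C_rand <- null$C_rand
          m$L_rand <- null$L_rand
          m$sigma <- sig
        } else {
          m$C_rand <- NA_real_
          m$L_rand <- NA_real_
          m$sigma <- NA_real_
        }
        dplyr::bind_cols(
          tibble::tibble(subject_id = rec$subject_id, group = rec$group,
                         case = case, n_epochs = n_ep),
          m[, c("threshold", "n_edges", "C", "L", "K_mean",
                "C_rand", "L_rand", "sigma", "connected")]
        )
      }) |> purrr::list_rbind()
    })
    purrr::list_rbind(rows)
  })
}

#' Compare two groups of sweep metrics with t-tests
#'
#' For every threshold and metric (C, L, K_mean, sigma), compares the two
#' groups' per-subject values with a two-sample t-test (Welch by default;
#' pooled-variance or paired on request). The t statistic is signed as
#' group a minus group b. No correction across thresholds is applied by
#' default, matching the per-threshold significance convention of the sweep;
#' `fdr = TRUE` adds a Benjamini-Hochberg adjusted column.
#'
#' @param table_a,table_b Tibbles from [subject_metrics()], same grid.
#' @param metrics Metric columns to compare.
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @param paired Paired test (subjects matched by position).
#' @param alpha Significance level for the `significant` flag.
#' @param fdr Add a `p_fdr` column (BH across thresholds, per metric).
#' @return A `nirs_sweep` tibble: one row per threshold x metric with group
#'   means, SDs, sizes, `t`, `p`, `significant`, and per-threshold
#'   disconnection counts. Group and case labels are kept as attributes.
#' @export
compare_groups <- function(table_a, table_b,
                           metrics = c("C", "L", "K_mean", "sigma"),
                           var_equal = FALSE, paired = FALSE,
                           alpha = 0.05, fdr = FALSE) {
  if (nrow(table_a) == 0 || nrow(table_b) == 0) {
    abort("Both metric tables must be nonempty.")
  }
  grid_a <- sort(unique(table_a$threshold))
  grid_b <- sort(unique(table_b$threshold))
  if (!isTRUE(all.equal(grid_a, grid_b))) {
    abort("The two tables use different threshold grids.")
  }
  n_subj <- function(tab) length(unique(tab$subject_id))
  if (n_subj(table_a) < 2 || n_subj(table_b) < 2) {
    abort("Each group needs at least 2 subjects.")
  }
  res <- purrr::map(grid_a, function(T) {
    a_t <- dplyr::filter(table_a, .data$threshold == T)
    b_t <- dplyr::filter(table_b, .data$threshold == T)
    purrr::map(metrics, function(m) {
      av <- a_t[[m]]
      bv <- b_t[[m]]
      if (paired) {
        keep <- is.finite(av) & is.finite(bv)
        av <- av[keep]; bv <- bv[keep]
      } else {
        av <- av[is.finite(av)]
        bv <- bv[is.finite(bv)]
      }
      if (length(av) < 2 || length(bv) < 2) {
        warn(sprintf("Fewer than 2 finite '%s' values at T = %g; t-test skipped.", m, T))
        tt <- list(statistic = NA_real_, p.value = NA_real_)
      } else {
        tt <- t.test(av, bv, var.equal = var_equal, paired = paired)
      }
      tibble::tibble(
        threshold = T, metric = m,
        mean_a = mean(av), sd_a = sd(av), n_a = length(av),
        mean_b = mean(bv), sd_b = sd(bv), n_b = length(bv),
        t = unname(tt$statistic), p = unname(tt$p.value),
        n_disconnected_a = sum(!a_t$connected),
        n_disconnected_b = sum(!b_t$connected)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (fdr) {
    res <- res |>
      dplyr::group_by(.data$metric) |>
      dplyr::mutate(p_fdr = p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup()
  }
  res$significant <- !is.na(res$p) & res$p < alpha
  attr(res, "groups") <- c(a = unique(table_a$group)[1],
                           b = unique(table_b$group)[1])
  attr(res, "cases") <- c(a = unique(table_a$case)[1],
                          b = unique(table_b$case)[1])
  attr(res, "alpha") <- alpha
  attr(res, "test") <- if (paired) "paired t" else if (var_equal) "Student t" else "Welch t"
  class(res) <- c("nirs_sweep", class(res))
  res
}

#' @export
print.nirs_sweep <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("<nirs_sweep> %s vs %s (%s), %d thresholds x %d metrics\n",
              g[["a"]], g[["b"]], attr(x, "test"),
              length(unique(x$threshold)), length(unique(x$metric))))
  NextMethod()
}
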