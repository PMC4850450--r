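test_that("threshold grid matches the sweep protocol", {
  grid <- threshold_grid()
  expect_equal(grid[1], 0.275)
  expect_equal(grid[length(grid)], 0.625)
  expect_length(grid, 1 + round((0.625 - 0.275) / 0.025))
  expect_equal(diff(grid), rep(0.025, 14), tolerance = 1e-12)
  expect_equal(threshold_grid(0.4, 0.4, 0.025), 0.4)
  expect_error(threshold_grid(step = 0), "positive")
  expect_error(threshold_grid(0.5, 0.4), "exceed")
})

test_that("grid bounds diagnostics use the exact critical-r relation", {
  set.seed(30)
  v <- cor(matrix(rnorm(200 * 24), ncol = 24))
  m <- as_corrmat(v, n_samples_used = 130)
  out <- check_bounds(list(m), n_samples = 130)
  t_crit <- qt(0.975, 128)
  r_crit <- t_crit / sqrt(128 + t_crit^2)
  expect_equal(out$r_crit, r_crit, tolerance = 1e-12)
  # closed-form inverse: t = r * sqrt((n-2)/(1-r^2)) at r = r_crit gives t_crit
  expect_equal(r_crit * sqrt(128 / (1 - r_crit^2)), t_crit, tolerance = 1e-10)
  # with huge n any nonzero threshold is significant
  out2 <- check_bounds(list(m), n_samples = 1e6)
  expect_equal(out2$t_min_ok, threshold_grid()[1])
  # all-|r|=1 matrices stay connected to the last grid value
  ones <- matrix(1, 10, 10)
  out3 <- check_bounds(list(as_corrmat(ones, n_samples_used = 130)))
  expect_equal(out3$t_max_ok, 0.625)
  expect_error(check_bounds(list(m), n_samples = 3), "at least 4")
})

test_that("subject_metrics yields one row per subject and threshold", {
  cfg <- tiny_config()
  cohort <- simulate_cohort(cfg)
  grp <- vapply(cohort, function(r) r$group, character(1))
  grid <- c(0.3, 0.4, 0.5)
  tab <- subject_metrics(cohort[grp == "spontaneous"], "win-win",
                         grid = grid, null_n = 10, seed = 2)
  expect_equal(nrow(tab), 2 * 3)
  expect_setequal(unique(tab$threshold), grid)
  expect_true(all(tab$C >= 0 & tab$C <= 1))
  expect_true(all(tab$K_mean >= 0 & tab$K_mean <= 23))
  expect_true(all(tab$L >= 1 | is.na(tab$L)))
  expect_true(all(tab$n_epochs == cfg$n_trials_per_case))
  # reproducible under the same seed
  tab2 <- subject_metrics(cohort[grp == "spontaneous"], "win-win",
                          grid = grid, null_n = 10, seed = 2)
  expect_identical(tab, tab2)
})

test_that("identical recordings give zero between-subject spread", {
  cfg <- tiny_config()
  rec <- simulate_recording(cfg, "S01", "spontaneous")
  recs <- list(rec, rec, rec)
  tab <- subject_metrics(recs, "win-win", grid = c(0.3, 0.5), null_n = 5,
                         seed = 3)
  spread <- tab |>
    dplyr::group_by(threshold) |>
    dplyr::summarise(dC = diff(range(C)), dL = diff(range(L)),
                     dK = diff(range(K_mean)))
  expect_true(all(spread$dC == 0))
  expect_true(all(spread$dL == 0))
  expect_true(all(spread$dK == 0))
})

test_that("group comparison matches closed-form t statistics", {
  a <- c(0.52, 0.61, 0.55, 0.58, 0.49)
  b <- c(0.44, 0.47, 0.51, 0.40, 0.46)
  cmp_w <- compare_groups(metric_table(a, "spontaneous"),
                          metric_table(b, "control"))
  cmp_s <- compare_groups(metric_table(a, "spontaneous"),
                          metric_table(b, "control"), var_equal = TRUE)
  for (T in c(0.3, 0.4)) {
    row_w <- cmp_w[cmp_w$threshold == T & cmp_w$metric == "C", ]
    expect_equal(row_w$t, oracle_t_welch(a, b), tolerance = 1e-10)
    expect_equal(row_w$mean_a, mean(a))
    expect_equal(row_w$sd_b, sd(b))
    row_s <- cmp_s[cmp_s$threshold == T & cmp_s$metric == "K_mean", ]
    expect_equal(row_s$t, oracle_t_pooled(2 * a, 2 * b), tolerance = 1e-10)
  }
  expect_equal(unique(cmp_w$n_a), 5)
})

test_that("comparing a table with itself gives t = 0 and p = 1", {
  a <- c(0.52, 0.61, 0.55, 0.58, 0.49)
  cmp <- compare_groups(metric_table(a, "spontaneous"),
                        metric_table(a, "control"))
  expect_true(all(abs(cmp$t) < 1e-12))
  expect_true(all(cmp$p > 1 - 1e-12))
  expect_false(any(cmp$significant))
})

test_that("swapping the group labels negates t and keeps p", {
  set.seed(31)
  a <- rnorm(8, 0.6, 0.05)
  b <- rnorm(8, 0.5, 0.08)
  ab <- compare_groups(metric_table(a, "g1"), metric_table(b, "g2"))
  ba <- compare_groups(metric_table(b, "g2"), metric_table(a, "g1"))
  expect_equal(ba$t, -ab$t, tolerance = 1e-12)
  expect_equal(ba$p, ab$p, tolerance = 1e-12)
})

test_that("comparison validates grids and group sizes", {
  a <- c(0.5, 0.6, 0.7)
  expect_error(compare_groups(metric_table(a, "g", threshold = c(0.3, 0.4)),
                              metric_table(a, "g", threshold = c(0.3, 0.5))),
               "different threshold grids")
  expect_error(compare_groups(metric_table(0.5, "g"), metric_table(a, "g")),
               "at least 2 subjects")
})

test_that("tidy and glance reshape the comparison faithfully", {
  a <- c(0.52, 0.61, 0.55, 0.58, 0.49)
  b <- c(0.44, 0.47, 0.51, 0.40, 0.46)
  cmp <- compare_groups(metric_table(a, "spontaneous"),
                        metric_table(b, "control"))
  td <- tidy(cmp)
  expect_equal(nrow(td), 2 * nrow(cmp))
  expect_setequal(unique(td$group), c("spontaneous", "control"))
  row <- td[td$group == "spontaneous" & td$metric == "C" &
              td$threshold == 0.3, ]
  expect_equal(row$mean, mean(a))
  gl <- glance(cmp)
  expect_equal(gl$n_thresholds, 2)
  expect_true(all(c("n_sig_C", "n_sig_sigma") %in% names(gl)))
  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
})
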