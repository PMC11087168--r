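test_that("run_grid produces the full record lattice deterministically", {
  cohort <- generate_cohort(cohort_spec(plans_per_site = 1))[1:2]
  spec <- list(resolution = 2, binary = TRUE)
  rec <- run_grid(cohort, parameters = c("mlc_offset", "mlc_transmission"),
                  percentiles = c(2.5, 97.5), grid_spec = spec)
  # plans x parameters x percentiles x endpoints
  expect_equal(nrow(rec), 2 * 2 * 2 * 7)
  expect_setequal(unique(rec$endpoint), planperturb:::endpoint_names())
  rec2 <- run_grid(cohort, parameters = c("mlc_offset", "mlc_transmission"),
                   percentiles = c(2.5, 97.5), grid_spec = spec)
  expect_identical(rec, rec2)
  # single plan/param/pct -> one record per endpoint
  rec3 <- run_grid(cohort[1], parameters = "mlc_offset", percentiles = 97.5,
                   grid_spec = spec)
  expect_equal(nrow(rec3), 7)
})

test_that("summarize_deviations aggregates means and maxima", {
  rec <- data.frame(plan_id = c("a", "b", "c"), site_label = "prostate",
                    parameter = "mlc_offset", percentile = 97.5,
                    endpoint = "ctv_mean", pct_deviation = c(1, 2, 3))
  s <- summarize_deviations(rec)
  expect_equal(nrow(s), 1)
  expect_equal(s$mean_dev, 2)
  expect_equal(s$max_abs_dev, 3)
  # empty input -> empty frame, not NaN rows
  expect_equal(nrow(summarize_deviations(rec[0, ])), 0)
  # partition: per-site groups cover all records
  s2 <- summarize_deviations(rec, by_site = TRUE)
  expect_equal(sum(s2$max_abs_dev == 3), 1)
})

test_that("parameter filter implements the >1% / >=10% rule exactly", {
  mk <- function(par, n_over, n_under) {
    data.frame(plan_id = sprintf("%s-%03d", par, seq_len(n_over + n_under)),
               site_label = "prostate", parameter = par, percentile = 97.5,
               endpoint = "ctv_mean",
               pct_deviation = c(rep(2, n_over), rep(0.5, n_under)))
  }
  rec <- rbind(mk("A", 50, 0), mk("B", 5, 0), mk("C", 45, 0))
  expect_setequal(filter_parameters(rec), c("A", "C"))
  # boundary: exactly 10% of the total is kept ("at least")
  rec2 <- rbind(mk("A", 90, 0), mk("B", 10, 0))
  expect_setequal(filter_parameters(rec2), c("A", "B"))
  # all below threshold -> empty with warning
  rec3 <- mk("A", 0, 10)
  expect_warning(out <- filter_parameters(rec3), "no perturbation")
  expect_length(out, 0)
})

test_that("OLS internals match stats::lm and the two-point closed form", {
  set.seed(4)
  x <- rnorm(25, 20, 5)
  y <- 2 - 0.05 * x + rnorm(25, 0, 0.3)
  f <- planperturb:::ols_fit(x, y)
  o <- oracle_ols(x, y)
  expect_equal(f$slope, o$slope, tolerance = 1e-9)
  expect_equal(f$intercept, o$intercept, tolerance = 1e-9)
  expect_equal(f$r_squared, o$r_squared, tolerance = 1e-9)
  # two points: line through them, R^2 = 1
  f2 <- planperturb:::ols_fit(c(10, 30), c(5, 1))
  expect_equal(f2$slope, (1 - 5) / (30 - 10))
  expect_equal(f2$intercept, 5 - f2$slope * 10)
  expect_equal(f2$r_squared, 1)
})

test_that("metric regressions: perfect fits, null fits and bookkeeping", {
  set.seed(11)
  ids <- sprintf("p%02d", 1:25)
  sites <- rep(c("prostate", "lung", "head_and_neck", "brain",
                 "mesothelioma"), each = 5)
  mg <- runif(25, 10, 48)
  mtab <- data.frame(plan_id = ids, mean_gap = mg, tgi = runif(25, 0, 0.5))
  # response stays positive over mg in [10, 48] so |.| keeps it linear
  rec <- data.frame(plan_id = ids, site_label = sites,
                    parameter = "mlc_offset", percentile = 97.5,
                    endpoint = "ctv_mean", pct_deviation = 5 - 0.05 * mg)
  fits <- fit_metric_regressions(rec, mtab, "mlc_offset")
  pooled <- fits[fits$site_label == "all" & fits$metric_name == "mean_gap", ]
  expect_equal(pooled$r_squared, 1, tolerance = 1e-12)
  expect_equal(pooled$slope, -0.05, tolerance = 1e-12)
  expect_equal(pooled$n, 25)
  site_fit <- fits[fits$site_label == "prostate" &
                     fits$metric_name == "mean_gap", ]
  expect_equal(site_fit$n, 5)
  # random response: pooled R^2 small (seeded null simulation)
  rec$pct_deviation <- sample(rec$pct_deviation)
  fits2 <- fit_metric_regressions(rec, mtab, "mlc_offset")
  expect_lt(fits2[fits2$site_label == "all" &
                    fits2$metric_name == "mean_gap", "r_squared"], 0.3)
})

test_that("rank_metrics orders schemes consistently and breaks ties by name", {
  fits <- data.frame(
    metric_name = rep(c("tgi", "mean_gap", "mcs"), each = 2),
    parameter = "mlc_offset",
    site_label = rep(c("prostate", "lung"), 3),
    slope = -1, intercept = 5,
    r_squared = c(1, 1, 1, 1, 0.2, 0.4),
    rmse = c(0.1, 0.1, 0.1, 0.1, 0.9, 0.8),
    n = 5, n_over_threshold = c(3, 3, 3, 3, 1, 1))
  rk <- rank_metrics(fits)
  # mean_gap and tgi tied at R^2 = 1: alphabetical tie-break
  expect_identical(rk$metric_name[rk$rank_mean_r2 == 1], "mean_gap")
  expect_identical(rk$metric_name[rk$rank_mean_r2 == 2], "tgi")
  expect_identical(rk$metric_name[rk$rank_mean_r2 == 3], "mcs")
  expect_true(all(sort(rk$rank_mean_r2) == 1:3))
  expect_true(all(sort(rk$rank_rmse) == 1:3))
})

test_that("threshold derivation inverts the fitted line", {
  th <- derive_threshold(list(slope = -0.1176, intercept = 6), 2)
  expect_equal(th$threshold, 34.0, tolerance = 0.02)
  expect_identical(th$direction, "above")
  th2 <- derive_threshold(list(slope = 0.02, intercept = 1), 2)
  expect_equal(th2$threshold, 50)
  expect_identical(th2$direction, "below")
  th3 <- derive_threshold(list(slope = 0, intercept = 1), 2)
  expect_true(is.na(th3$threshold))
  expect_identical(th3$direction, "none")
})

test_that("filter is idempotent on an already-filtered record set", {
  mk <- function(par, n) data.frame(
    plan_id = sprintf("%s-%03d", par, seq_len(n)), site_label = "lung",
    parameter = par, percentile = 2.5, endpoint = "ctv_mean",
    pct_deviation = rep(3, n))
  rec <- rbind(mk("A", 50), mk("B", 5), mk("C", 45))
  kept <- filter_parameters(rec)
  rec_f <- rec[rec$parameter %in% kept, ]
  expect_setequal(filter_parameters(rec_f), kept)
})
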