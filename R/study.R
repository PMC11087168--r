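# Study pipeline: perturbation grid -> deviation records -> parameter filter
# -> per-metric regressions -> ranking -> complexity thresholds.

#' Run the perturbation grid over a cohort
#'
#' For each plan, the baseline (50th-percentile) dose-proxy map is computed
#' once; each (parameter, percentile) perturbation is then evaluated against
#' it, producing one record per endpoint. The default grid of 10 parameters
#' at 4 percentiles over a 25-plan cohort yields the canonical 1,000
#' perturbation cells.
#'
#' @param cohort List of [rt_plan()] objects with ROIs.
#' @param table Percentile table ([default_percentile_table()] layout).
#' @param parameters Parameter names to perturb (default: all ten).
#' @param percentiles Percentile levels (default `c(2.5, 25, 75, 97.5)`).
#' @param grid_spec Fluence options passed to [accumulate_plan_map()].
#' @param verbose Print one line per plan.
#' @return data.frame of deviation records: `plan_id`, `site_label`,
#'   `parameter`, `percentile`, `endpoint`, `pct_deviation`.
#' @export
run_grid <- function(cohort, table = default_percentile_table(),
                     parameters = default_percentile_table()$parameter,
                     percentiles = c(2.5, 25, 75, 97.5),
                     grid_spec = list(resolution = 0.5, binary = FALSE),
                     verbose = FALSE) {
  stopifnot(length(cohort) >= 1)
  baseline <- model_from_percentiles(table)
  rows <- vector("list", 0)
  for (plan in cohort) {
    if (is.null(plan$rois)) stop("plan ", plan$plan_id, " has no ROIs")
    if (verbose) message("plan ", plan$plan_id)
    bmap <- accumulate_plan_map(plan, baseline, grid_spec)
    for (par in parameters) {
      for (pct in percentiles) {
        model <- model_from_percentiles(table,
                                        stats::setNames(list(pct), par))
        dev <- dose_deviation(plan, model, baseline, rois = plan$rois,
                              grid_spec = grid_spec, baseline_map = bmap)
        rows[[length(rows) + 1]] <- data.frame(
          plan_id = plan$plan_id, site_label = plan$site_label,
          parameter = par, percentile = pct,
          endpoint = names(dev), pct_deviation = unname(dev),
          stringsAsFactors = FALSE, row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize deviation records
#'
#' Mean signed deviation and maximum absolute deviation per
#' (parameter, percentile, endpoint) group, optionally split by site.
#'
#' @param records data.frame from [run_grid()].
#' @param by_site Also group by `site_label`.
#' @return data.frame with `mean_dev` and `max_abs_dev` per group; empty
#'   groups are absent rather than NaN.
#' @export
summarize_deviations <- function(records, by_site = FALSE) {
  keys <- c("parameter", "percentile", "endpoint",
            if (by_site) "site_label")
  records <- records[is.finite(records$pct_deviation), , drop = FALSE]
  if (!nrow(records)) {
    return(data.frame())
  }
  agg1 <- stats::aggregate(records["pct_deviation"], records[keys], mean)
  names(agg1)[names(agg1) == "pct_deviation"] <- "mean_dev"
  agg2 <- stats::aggregate(list(max_abs_dev = abs(records$pct_deviation)),
                           records[keys], max)
  merge(agg1, agg2, by = keys)
}

#' Apply the parameter contribution filter
#'
#' Counts the (plan, parameter, percentile) cells whose mean-CTV deviation
#' exceeds `dev_threshold` in absolute value, and keeps the parameters
#' responsible for at least `contribution_threshold` of the grand total of
#' such cells ("at least" - the boundary count is kept).
#'
#' @param records data.frame from [run_grid()].
#' @param dev_threshold Percent deviation threshold (default 1).
#' @param contribution_threshold Fraction of the grand total (default 0.10).
#' @return Character vector of retained parameter names (possibly empty,
#'   with a warning when no cell exceeds the threshold).
#' @export
filter_parameters <- function(records, dev_threshold = 1,
                              contribution_threshold = 0.10) {
  r <- records[records$endpoint == "ctv_mean" &
                 is.finite(records$pct_deviation) &
                 abs(records$pct_deviation) > dev_threshold, , drop = FALSE]
  if (!nrow(r)) {
    warning("no perturbation exceeded the deviation threshold")
    return(character(0))
  }
  counts <- table(r$parameter)
  total <- sum(counts)
  names(counts)[counts >= contribution_threshold * total]
}

ols_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                rmse = NA_real_, n = n))
  }
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  syy <- sum((y - my)^2)
  r2 <- if (syy == 0) NA_real_ else 1 - sum(resid^2) / syy
  list(slope = slope, intercept = intercept, r_squared = r2,
       rmse = sqrt(mean(resid^2)), n = n)
}

#' Regress plan sensitivity on each complexity metric
#'
#' Per plan and parameter, the response is the maximum over percentile
#' levels of the absolute mean-CTV deviation; per (metric, parameter) an
#' ordinary least-squares line of that response on the metric value is
#' fitted per site and pooled over sites (`site_label = "all"`). Plans with
#' an undefined metric are excluded; fits need at least 3 plans; zero metric
#' variance gives an NA R-squared.
#'
#' @param records data.frame from [run_grid()].
#' @param metrics Named list (or data.frame rows) mapping `plan_id` to a
#'   metric vector from [plan_metrics()], or the data.frame produced by
#'   [cohort_metrics()].
#' @param parameters Parameters to fit (pre-filtered via
#'   [filter_parameters()]); PDD is excluded by default upstream because its
#'   impact follows patient geometry rather than plan complexity.
#' @param dev_threshold Threshold (% deviation) used for the per-fit count
#'   of sensitive plans feeding the weighted ranking.
#' @return data.frame with `metric_name`, `parameter`, `site_label`,
#'   `slope`, `intercept`, `r_squared`, `rmse`, `n`, `n_over_threshold`.
#' @export
fit_metric_regressions <- function(records, metrics, parameters,
                                   dev_threshold = 1) {
  mtab <- if (is.data.frame(metrics)) metrics else do.call(rbind, lapply(
    names(metrics), function(id) {
      data.frame(plan_id = id, as.data.frame(metrics[[id]]),
                 stringsAsFactors = FALSE)
    }))
  r <- records[records$endpoint == "ctv_mean" &
                 records$parameter %in% parameters &
                 is.finite(records$pct_deviation), , drop = FALSE]
  resp <- stats::aggregate(list(y = abs(r$pct_deviation)),
                           r[c("plan_id", "site_label", "parameter")], max)
  mcols <- mtab[, c("plan_id", intersect(metric_names(), names(mtab))),
                drop = FALSE]
  out <- list()
  for (par in parameters) {
    rp <- resp[resp$parameter == par, , drop = FALSE]
    rp <- merge(rp, mcols, by = "plan_id")
    for (site in c(unique(rp$site_label), "all")) {
      sub <- if (site == "all") rp else rp[rp$site_label == site, , drop = FALSE]
      for (met in intersect(metric_names(), names(mtab))) {
        x <- sub[[met]]; y <- sub$y
        keep <- is.finite(x) & is.finite(y)
        if (sum(keep) < 3) next
        f <- ols_fit(x[keep], y[keep])
        out[[length(out) + 1]] <- data.frame(
          metric_name = met, parameter = par, site_label = site,
          slope = f$slope, intercept = f$intercept, r_squared = f$r_squared,
          rmse = f$rmse, n = f$n,
          n_over_threshold = sum(y[keep] > dev_threshold),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank metrics by regression quality
#'
#' Three schemes over the per-site fits: unweighted mean R-squared (primary,
#' higher is better), mean R-squared weighted by each fit's count of
#' plans above the deviation threshold, and mean residual RMSE (lower is
#' better). Ties break by metric name (alphabetical).
#'
#' @param results data.frame from [fit_metric_regressions()].
#' @param include_pooled Include the pooled `site_label == "all"` fits in
#'   the averages (default `FALSE`: per-site fits only, pooled fits are
#'   reported separately).
#' @return data.frame with one row per metric: `mean_r2`, `weighted_r2`,
#'   `rmse`, and `rank_mean_r2`, `rank_weighted_r2`, `rank_rmse`.
#' @export
rank_metrics <- function(results, include_pooled = FALSE) {
  r <- results[is.finite(results$r_squared), , drop = FALSE]
  if (!include_pooled) r <- r[r$site_label != "all", , drop = FALSE]
  sp <- split(r, r$metric_name)
  tab <- do.call(rbind, lapply(names(sp), function(met) {
    s <- sp[[met]]
    wr <- if (sum(s$n_over_threshold) > 0)
      sum(s$r_squared * s$n_over_threshold) / sum(s$n_over_threshold)
    else NA_real_
    data.frame(metric_name = met, mean_r2 = mean(s$r_squared),
               weighted_r2 = wr, rmse = mean(s$rmse), n_fits = nrow(s),
               stringsAsFactors = FALSE)
  }))
  o <- order(tab$metric_name)          # alphabetical tie-break baked in
  tab <- tab[o, , drop = FALSE]
  tab$rank_mean_r2 <- rank(-tab$mean_r2, ties.method = "first")
  tab$rank_weighted_r2 <- rank(-tab$weighted_r2, ties.method = "first")
  tab$rank_rmse <- rank(tab$rmse, ties.method = "first")
  tab <- tab[order(tab$rank_mean_r2), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Derive a complexity threshold from a fitted sensitivity line
#'
#' Inverts `dose = intercept + slope * metric` at the dose limit:
#' `threshold = (dose_limit - intercept) / slope`. The direction flag states
#' on which side of the threshold plans are robust: `"above"` for a
#' negative slope (e.g. mean MLC gap - bigger gaps are safer), `"below"`
#' for a positive slope (e.g. TGi - smoother apertures are safer).
#'
#' @param result One row of [fit_metric_regressions()] output (or any list
#'   with `slope` and `intercept`).
#' @param dose_limit Dose-deviation limit (%).
#' @param slope_tol Slopes smaller than this in absolute value yield a
#'   no-threshold marker.
#' @return List with `threshold` (NA when no threshold exists) and
#'   `direction` (`"above"`, `"below"` or `"none"`).
#' @export
#' @examples
#' derive_threshold(list(slope = -0.1176, intercept = 6), 2)  # 34.0, above
derive_threshold <- function(result, dose_limit, slope_tol = 1e-8) {
  if (!is.finite(result$slope) || abs(result$slope) < slope_tol) {
    return(list(threshold = NA_real_, direction = "none"))
  }
  list(threshold = (dose_limit - result$intercept) / result$slope,
       direction = if (result$slope < 0) "above" else "below")
}
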