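# Study configuration, one-command pipeline, and report generation. Every
# figure has a machine-readable CSV twin; plotting functions do no analysis.

#' Complexity metrics table for a cohort
#'
#' @param cohort List of [rt_plan()] objects.
#' @return data.frame: `plan_id`, `site_label` and the 18 metric columns of
#'   [metric_names()].
#' @export
cohort_metrics <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, function(plan) {
    mv <- plan_metrics(plan)
    cbind(data.frame(plan_id = plan$plan_id, site_label = plan$site_label,
                     stringsAsFactors = FALSE),
          as.data.frame(mv))
  }))
  rownames(out) <- NULL
  out
}

#' Study configuration
#'
#' @param out_dir Output directory for CSV artifacts and figures.
#' @param master_seed Master seed for cohort generation.
#' @param plans_per_site Plans per anatomical site.
#' @param parameters Beam-model parameters to perturb.
#' @param percentiles Percentile levels.
#' @param resolution Fluence grid resolution (mm/pixel).
#' @param binary Binary-fluence mode switch.
#' @param exclude_pdd Exclude PDD from metric regressions (default `TRUE`;
#'   its dose impact follows patient geometry, not plan complexity).
#' @param percentile_table Percentile table data.frame.
#' @param dose_limits Dose-deviation limits (%) for threshold derivation.
#' @return A `study_config` list.
#' @export
study_config <- function(out_dir, master_seed = 20240314, plans_per_site = 5,
                         parameters = default_percentile_table()$parameter,
                         percentiles = c(2.5, 25, 75, 97.5),
                         resolution = 0.5, binary = FALSE,
                         exclude_pdd = TRUE,
                         percentile_table = default_percentile_table(),
                         dose_limits = c(2, 4)) {
  structure(list(out_dir = out_dir, master_seed = as.integer(master_seed),
                 plans_per_site = plans_per_site, parameters = parameters,
                 percentiles = percentiles, resolution = resolution,
                 binary = binary, exclude_pdd = exclude_pdd,
                 percentile_table = percentile_table,
                 dose_limits = dose_limits),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognized keys mirror the [study_config()] arguments; an optional
#' `percentile_table` key points at a YAML file for
#' [read_percentile_table()].
#'
#' @param path YAML file path.
#' @param out_dir Output directory (overrides any `out_dir` key).
#' @return A `study_config`.
#' @export
read_study_config <- function(path, out_dir = NULL) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$percentile_table) && is.character(obj$percentile_table)) {
    obj$percentile_table <- read_percentile_table(
      file.path(dirname(path), obj$percentile_table))
  }
  if (!is.null(out_dir)) obj$out_dir <- out_dir
  keep <- intersect(names(obj), names(formals(study_config)))
  do.call(study_config, obj[keep])
}

write_stage_csv <- function(df, path) {
  tmp <- paste0(path, ".partial")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  path
}

read_stage_csv <- function(path) {
  if (!file.exists(path)) return(NULL)
  tryCatch(suppressWarnings(utils::read.csv(path, stringsAsFactors = FALSE)),
           error = function(e) NULL)
}

#' Run the complete study pipeline
#'
#' generate -> metrics -> perturbation grid -> filter -> regressions ->
#' ranking -> thresholds, writing `deviations.csv`, `metrics.csv`,
#' `regressions.csv`, `ranking.csv`, `thresholds.csv` and `study_log.txt`
#' into `config$out_dir`. Stages whose CSV already exists are skipped unless
#' `force = TRUE` (corrupted CSVs are re-run with a warning).
#'
#' @param config A [study_config()].
#' @param force Recompute cached stages.
#' @return Invisibly, a list with the cohort and all result tables.
#' @export
run_study <- function(config, force = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid_spec <- list(resolution = config$resolution, binary = config$binary)
  log_path <- file.path(config$out_dir, "study_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", file = log_path,
                               append = TRUE, sep = "")
  cat(sprintf("planperturb study  seed=%d  resolution=%.2f  binary=%s\n",
              config$master_seed, config$resolution, config$binary),
      file = log_path)
  logline("config hash: %08x", sum(utf8ToInt(paste(
    paste(config$parameters, collapse = ","), config$master_seed,
    config$resolution, config$binary))))

  cohort <- generate_cohort(cohort_spec(plans_per_site = config$plans_per_site,
                                        master_seed = config$master_seed))
  logline("cohort: %d plans", length(cohort))

  met_path <- file.path(config$out_dir, "metrics.csv")
  metrics <- if (!force) read_stage_csv(met_path) else NULL
  if (is.null(metrics) || !all(metric_names() %in% names(metrics))) {
    if (file.exists(met_path) && !force)
      warning("metrics.csv unreadable or incomplete; recomputing stage")
    metrics <- cohort_metrics(cohort)
    write_stage_csv(metrics, met_path)
  }

  dev_path <- file.path(config$out_dir, "deviations.csv")
  records <- if (!force) read_stage_csv(dev_path) else NULL
  if (is.null(records) || !"pct_deviation" %in% names(records)) {
    if (file.exists(dev_path) && !force)
      warning("deviations.csv unreadable; recomputing stage")
    records <- run_grid(cohort, config$percentile_table, config$parameters,
                        config$percentiles, grid_spec)
    write_stage_csv(records, dev_path)
  }

  kept <- filter_parameters(records)
  if (config$exclude_pdd) kept <- setdiff(kept, "pdd_slope_err")
  logline("parameters kept by the >1%%/>=10%% filter: %s",
          paste(kept, collapse = ", "))

  fits <- fit_metric_regressions(records, metrics, kept)
  write_stage_csv(fits, file.path(config$out_dir, "regressions.csv"))
  ranking <- rank_metrics(fits)
  write_stage_csv(ranking, file.path(config$out_dir, "ranking.csv"))

  thr_rows <- list()
  pooled <- fits[fits$site_label == "all", , drop = FALSE]
  for (k in seq_len(nrow(pooled))) {
    for (lim in config$dose_limits) {
      th <- derive_threshold(pooled[k, ], lim)
      thr_rows[[length(thr_rows) + 1]] <- data.frame(
        metric_name = pooled$metric_name[k], parameter = pooled$parameter[k],
        dose_limit = lim, threshold = th$threshold,
        direction = th$direction, stringsAsFactors = FALSE)
    }
  }
  thresholds <- do.call(rbind, thr_rows)
  write_stage_csv(thresholds, file.path(config$out_dir, "thresholds.csv"))
  logline("done: %d records, %d fits", nrow(records), nrow(fits))

  invisible(list(cohort = cohort, metrics = metrics, records = records,
                 kept_parameters = kept, fits = fits, ranking = ranking,
                 thresholds = thresholds))
}

#' Generate figures and summary tables from a results directory
#'
#' Writes PNG figures with machine-readable CSV twins: mean/max CTV
#' deviation bars per parameter and percentile, per-site deviation panels,
#' an R-squared box plot across the 18 metrics, and the threshold table.
#'
#' @param results_dir Directory holding the CSVs from [run_study()].
#' @param out_dir Output directory for figures (default `results_dir`).
#' @return Character vector of files written.
#' @export
make_report <- function(results_dir, out_dir = results_dir) {
  need <- file.path(results_dir,
                    c("deviations.csv", "regressions.csv", "thresholds.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing report inputs: ", paste(basename(missing), collapse = ", "))
  records <- utils::read.csv(need[1], stringsAsFactors = FALSE)
  fits <- utils::read.csv(need[2], stringsAsFactors = FALSE)
  if (!nrow(records)) stop("deviations.csv is empty; nothing to report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  # mean/max CTV deviation per parameter x percentile
  summ <- summarize_deviations(records)
  summ <- summ[summ$endpoint == "ctv_mean", , drop = FALSE]
  csv1 <- file.path(out_dir, "fig_deviation_by_parameter.csv")
  utils::write.csv(summ, csv1, row.names = FALSE)
  png1 <- file.path(out_dir, "fig_deviation_by_parameter.png")
  grDevices::png(png1, width = 1100, height = 650)
  op <- graphics::par(mar = c(9, 4, 2, 1))
  lab <- paste(summ$parameter, summ$percentile)
  graphics::barplot(summ$mean_dev, names.arg = lab, las = 2,
                    ylab = "mean CTV deviation (%)",
                    main = "Dose perturbation vs baseline (50th pct)")
  graphics::par(op)
  grDevices::dev.off()
  written <- c(written, csv1, png1)

  # per-site deviation panels
  summ_s <- summarize_deviations(records, by_site = TRUE)
  summ_s <- summ_s[summ_s$endpoint == "ctv_mean", , drop = FALSE]
  csv2 <- file.path(out_dir, "fig_deviation_by_site.csv")
  utils::write.csv(summ_s, csv2, row.names = FALSE)
  png2 <- file.path(out_dir, "fig_deviation_by_site.png")
  sites <- unique(summ_s$site_label)
  grDevices::png(png2, width = 1400, height = 350 * ceiling(length(sites) / 2))
  op <- graphics::par(mfrow = c(ceiling(length(sites) / 2), 2),
                      mar = c(8, 4, 2, 1))
  for (s in sites) {
    sub <- summ_s[summ_s$site_label == s, , drop = FALSE]
    graphics::barplot(sub$mean_dev,
                      names.arg = paste(sub$parameter, sub$percentile),
                      las = 2, ylab = "mean CTV dev (%)", main = s)
  }
  graphics::par(op)
  grDevices::dev.off()
  written <- c(written, csv2, png2)

  # R^2 box plot across metrics (per-site fits)
  per_site <- fits[fits$site_label != "all" & is.finite(fits$r_squared), ,
                   drop = FALSE]
  csv3 <- file.path(out_dir, "fig_r2_by_metric.csv")
  utils::write.csv(per_site[c("metric_name", "parameter", "site_label",
                              "r_squared")], csv3, row.names = FALSE)
  png3 <- file.path(out_dir, "fig_r2_by_metric.png")
  grDevices::png(png3, width = 1200, height = 600)
  op <- graphics::par(mar = c(11, 4, 2, 1))
  graphics::boxplot(r_squared ~ metric_name, data = per_site, las = 2,
                    ylab = expression(R^2), xlab = "",
                    main = "Fit quality per complexity metric")
  graphics::par(op)
  grDevices::dev.off()
  written <- c(written, csv3, png3)

  file.copy(need[3], file.path(out_dir, "table_thresholds.csv"),
            overwrite = TRUE)
  written <- c(written, file.path(out_dir, "table_thresholds.csv"))
  written
}

#' Write a cohort to disk as DICOM RT Plan and JSON files
#'
#' @param cohort List of plans.
#' @param dir Output directory.
#' @param formats Any of `"dicom"`, `"json"`.
#' @return Paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir, formats = c("dicom", "json")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (plan in cohort) {
    if ("dicom" %in% formats) {
      p <- file.path(dir, sprintf("RP.%s.dcm", plan$plan_id))
      write_rtplan(plan, p)
      paths <- c(paths, p)
    }
    if ("json" %in% formats) {
      p <- file.path(dir, sprintf("%s.json", plan$plan_id))
      plan_to_json(plan, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
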