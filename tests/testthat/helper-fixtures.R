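# Shared fixtures. Plans are always generated in code at test time.

# Small mixed-technique probe presets for oracle tests (<= 50 CPs per beam).
probe_presets <- function() {
  list(
    site_preset("other", "VMAT-arc", 1, 20, c(15, 25), c(0.2, 0.8), 80, 70,
                c(150, 250), 0.6, 0.3, arc_span = 180),
    site_preset("other", "VMAT-arc", 1, 30, c(25, 40), c(0.05, 0.5), 90, 60,
                c(200, 300), 0.25, 0.2, arc_span = 340),
    site_preset("other", "static-IMRT", 2, 8, c(12, 20), c(0.2, 0.9), 100, 90,
                c(80, 120), 0.7, 0.35)
  )
}

probe_plans <- function(n = 10) {
  ps <- probe_presets()
  lapply(seq_len(n), function(k) {
    generate_plan(ps[[(k - 1) %% length(ps) + 1]], seed = 1000 + k)
  })
}

# Insert midpoint control points into a beam (halves the MU weight of each
# interval); used by the refinement-invariance property.
refine_beam <- function(bm) {
  cps <- bm$control_points
  out <- list(cps[[1]])
  for (i in 2:length(cps)) {
    a <- cps[[i - 1]]; b <- cps[[i]]
    mid <- a
    for (f in c("cumulative_mu_fraction", "gantry_angle", "bank_A", "bank_B",
                "nominal_time"))
      mid[[f]] <- (a[[f]] + b[[f]]) / 2
    mid$dose_rate <- b$dose_rate
    out[[length(out) + 1]] <- mid
    out[[length(out) + 1]] <- b
  }
  bm$control_points <- out
  bm
}

# Default-seed cohort and its 3-parameter study grid, computed once and
# shared by the acceptance tests (criteria 6 and 8). Package-default 0.5 mm
# resolution, full physics.
.study_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.study_cache$cohort))
    .study_cache$cohort <- generate_cohort(cohort_spec())
  .study_cache$cohort
}

acceptance_metrics <- function() {
  if (is.null(.study_cache$metrics))
    .study_cache$metrics <- cohort_metrics(acceptance_cohort())
  .study_cache$metrics
}

acceptance_grid <- function() {
  if (is.null(.study_cache$grid)) {
    cohort <- acceptance_cohort()
    .study_cache$grid <- list(
      records = run_grid(cohort,
                         parameters = c("mlc_offset", "mlc_transmission",
                                        "leaf_tip_width"),
                         grid_spec = list(resolution = 0.5, binary = FALSE)),
      metrics = acceptance_metrics()
    )
  }
  .study_cache$grid
}
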