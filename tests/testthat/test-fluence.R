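test_that("percentile table seeding and model construction", {
  tab <- default_percentile_table()
  m <- model_from_percentiles(tab, list(mlc_offset = 97.5))
  expect_identical(m$mlc_offset, 0.116)
  expect_identical(model_from_percentiles(tab,
    list(mlc_transmission = 2.5))$mlc_transmission, 0.007)
  # no overrides -> baseline, deviation against itself is zero
  base <- model_from_percentiles(tab)
  expect_identical(base$mlc_offset, 0.040)
  expect_identical(base$mlc_transmission, 0.018)
  expect_identical(base$leaf_tip_width, 0.320)
  expect_error(model_from_percentiles(tab, list(nonsense = 50)),
               "unknown parameter")
  expect_error(model_from_percentiles(tab, list(mlc_offset = 60)),
               "unknown percentile")
  bad <- tab
  bad$p75[1] <- -1
  expect_error(model_from_percentiles(bad), "monotone")
})

test_that("percentile table YAML round trip", {
  f <- withr::local_tempfile(fileext = ".yaml")
  tab <- default_percentile_table()
  yaml::write_yaml(stats::setNames(
    lapply(seq_len(nrow(tab)), function(i) unname(unlist(tab[i, -1]))),
    tab$parameter), f)
  tab2 <- read_percentile_table(f)
  expect_equal(tab2[order(tab2$parameter), -1][["p50"]],
               tab[order(tab$parameter), -1][["p50"]])
})

test_that("effective leaf positions follow the offset/gain/curvature law", {
  cp <- control_point(1, 0, c(-50, 0, 30, rep(-100, 57)),
                      c(50, 0.5, 80, rep(100, 57)), -150, 150, -200, 200)
  # offset only: every gap grows by 2 * offset
  m <- null_beam_model()
  m$mlc_offset <- 0.04
  e <- effective_leaf_positions(cp, m)
  expect_equal(e$bank_B - e$bank_A, (cp$bank_B - cp$bank_A) + 0.8,
               tolerance = 1e-12)
  # gain only: tip at x = 0 unmoved
  m2 <- null_beam_model()
  m2$mlc_gain <- 0.02
  e2 <- effective_leaf_positions(cp, m2)
  expect_equal(e2$bank_A[2], cp$bank_A[2])
  # curvature only 0.01 /cm: tip at 5 cm moves outward 0.25 cm = 2.5 mm
  m3 <- null_beam_model()
  m3$mlc_curvature <- 0.01
  cp3 <- control_point(1, 0, c(50, rep(-100, 59)), c(80, rep(100, 59)),
                       -150, 150, -200, 200)
  e3 <- effective_leaf_positions(cp3, m3)
  expect_equal(e3$bank_A[1], 50 - 2.5)
})

test_that("control-point fluence: open, blocked and tip-ramp values", {
  geo <- machine_geometry()
  cp <- control_point(1, 0, rep(-20, 60), rep(20, 60), -30, 30, -30, 30)
  m <- beam_model_params(mlc_offset = 0, source_sigma = 0, tg_width = 0,
                         leaf_tip_width = 0.2, mlc_transmission = 0.018)
  g <- fluence_grid(c(-40, 40), c(-40, 40), 0.5)
  fl <- control_point_fluence(cp, m, g, geo)
  at <- function(x, y) fl$values[which.min(abs(fl$ys - y)),
                                 which.min(abs(fl$xs - x))]
  expect_equal(at(0, 0), 1)                       # mid-aperture
  expect_equal(at(-25, 0), 0.018)                 # behind leaf, past the ramp
  expect_equal(at(25, 0), 0.018)
  expect_equal(at(0, 35), 0)                      # outside jaws (y)
  # inside the tip ramp: linear between 1 at the tip and T at tip + width,
  # evaluated at the actual pixel center
  px <- fl$xs[which.min(abs(fl$xs - 21))]
  expect_equal(at(21, 0), 0.018 + (1 - 0.018) * (20 + 2 - px) / 2,
               tolerance = 1e-9)
  # undersampling refused
  g2 <- fluence_grid(c(-40, 40), c(-40, 40), 2)
  expect_error(control_point_fluence(cp, m, g2, geo), "undersamples")
})

test_that("tip-ramp excess fluence matches the analytic integral", {
  # excess over a sharp-edged model per unit edge length = w * (1 - T) / 2
  geo <- machine_geometry()
  cp <- control_point(1, 0, rep(-20, 60), rep(20, 60), -60, 60, -50, 50)
  res <- 0.05
  g <- fluence_grid(c(-35, 35), c(-2.5, 2.5), res)
  Tfr <- 0.018
  ramp <- beam_model_params(source_sigma = 0, tg_width = 0,
                            leaf_tip_width = 0.4, mlc_transmission = Tfr)
  sharp <- beam_model_params(source_sigma = 0, tg_width = 0,
                             leaf_tip_width = 0, mlc_transmission = Tfr)
  fr <- control_point_fluence(cp, ramp, g, geo)
  fs <- control_point_fluence(cp, sharp, g, geo)
  row <- which.min(abs(g$ys - 0))
  excess <- sum(fr$values[row, ] - fs$values[row, ]) * res
  expect_equal(excess, 2 * 4 * (1 - Tfr) / 2, tolerance = 0.02)  # two tips
})

test_that("tongue-and-groove strips suppress fluence along exposed sides", {
  geo <- machine_geometry()
  A <- rep(-200, 60); B <- rep(-200, 60)
  A[30] <- -20; B[30] <- 20      # rows y in [-5, 0]
  A[31] <- -10; B[31] <- 10      # rows y in [0, 5]
  cp <- control_point(1, 0, A, B, -50, 50, -5, 5)
  m <- beam_model_params(source_sigma = 0, tg_width = 0.1,
                         leaf_tip_width = 0, mlc_transmission = 0.02)
  g <- fluence_grid(c(-30, 30), c(-5, 5), 0.25)
  fl <- control_point_fluence(cp, m, g, geo)
  at <- function(x, y) fl$values[which.min(abs(fl$ys - y)),
                                 which.min(abs(fl$xs - x))]
  # exposed side of pair 30 (x in [-20,-10) or (10,20]) just below y = 0
  expect_equal(at(-15, -0.4), 0.02)
  # same x but well inside pair 30's row: open
  expect_equal(at(-15, -3), 1)
  # x open in both rows: no strip
  expect_equal(at(0, -0.4), 1)
})

test_that("plan map: MU scaling invariances and plateau uniformity", {
  # CP step (sweep - gap)/(n_cp - 1) at or below the pixel size keeps the
  # Riemann ripple of the swept box below the 0.5% plateau contract
  sw <- make_sliding_window(20, 100, 201, 80, 150)
  m <- null_beam_model()
  spec <- list(resolution = 0.5, binary = TRUE)
  map1 <- accumulate_plan_map(sw, m, spec)
  # two identical beams: identical normalized map
  dbl <- sw
  dbl$beams <- c(sw$beams, sw$beams)
  map2 <- accumulate_plan_map(dbl, m, spec)
  expect_equal(map2$values, map1$values, tolerance = 1e-12)
  # interior plateau uniform within 0.5%
  mask <- planperturb:::roi_mask(map1, c(-25, 25, -35, 35))
  vals <- map1$values[mask]
  expect_lt(diff(range(vals)) / mean(vals), 0.005)
})

test_that("roi endpoints: uniform map, percentile arithmetic, coverage", {
  rois <- roi_set(ctv = c(-10, 10, -10, 10), oar_parallel = c(15, 25, -10, 10),
                  oar_serial = c(-25, -15, -10, 10))
  g <- fluence_grid(c(-30, 30), c(-15, 15), 1)
  g$values[] <- 2
  ep <- roi_endpoints(g, rois)
  for (nm in c("ctv_mean", "ctv_min", "ctv_max", "ctv_d95", "oar_mean",
               "oar_near_max"))
    expect_equal(ep[[nm]], 2, label = nm)
  expect_equal(ep$coverage, 1)
  # 20 of 1000 pixels at 2v -> near-max 2v
  set.seed(1)
  g2 <- fluence_grid(c(-25, 25), c(-10, 10), 1)
  g2$values[] <- 1
  hot <- sample(which(planperturb:::roi_mask(g2, rois$oar_serial)), 20)
  g2$values[hot] <- 2
  n_ser <- sum(planperturb:::roi_mask(g2, rois$oar_serial))
  expect_gte(n_ser, 100)
  ep2 <- roi_endpoints(g2, rois)
  expect_equal(ep2$oar_near_max, 2)
  # empty ROI errors
  bad <- roi_set(ctv = c(500, 510, 0, 1), oar_parallel = c(15, 25, -10, 10),
                 oar_serial = c(-25, -15, -10, 10))
  expect_error(roi_endpoints(g, bad), "empty ROI")
})

test_that("transmission deviation is affine for fully-blocked ROIs", {
  sw <- make_sliding_window(20, 120, 51, 100, 200)
  base <- null_beam_model()
  base$mlc_transmission <- 0.018
  spec <- list(resolution = 0.5, binary = TRUE)
  bmap <- accumulate_plan_map(sw, base, spec)
  tr <- c(0.007, 0.015, 0.022, 0.025)
  devs <- vapply(tr, function(t) {
    m <- base
    m$mlc_transmission <- t
    dose_deviation(sw, m, base, grid_spec = spec,
                   baseline_map = bmap)[["oar_mean"]]
  }, numeric(1))
  fit <- oracle_ols(tr, devs)
  expect_gt(fit$r_squared, 0.999)
  # exact affine value for the pure-transmission region
  expect_equal(devs[4], (0.025 - 0.018) / 0.018 * 100, tolerance = 1e-6)
})

test_that("dosimetric modifiers move endpoints in the right direction", {
  sw <- make_sliding_window(25, 100, 41, 80, 150)
  base <- beam_model_params()
  spec <- list(resolution = 1, binary = FALSE)
  bmap <- accumulate_plan_map(sw, base, spec)
  # output factor: positive error raises every endpoint of this small field
  m1 <- base; m1$output_factor_err <- 0.01
  d1 <- dose_deviation(sw, m1, base, grid_spec = spec, baseline_map = bmap)
  expect_lt(d1[["ctv_mean"]], 0)  # A_eq < 100 mm here, s(A_eq) < 0
  # PDD slope: CTV at default 10 cm depth is unaffected, but a shifted
  # depth scales the readout
  rois2 <- sw$rois
  rois2$ctv_depth <- 14
  m2 <- base; m2$pdd_slope_err <- 0.004
  d2 <- dose_deviation(sw, m2, base, rois = rois2, grid_spec = spec,
                       baseline_map = bmap)
  expect_equal(d2[["ctv_mean"]], 100 * (1 + 0.004 * 4 - 1), tolerance = 1e-6)
  # off-axis: positive error raises the serial OAR (off-axis) more than CTV
  m3 <- base; m3$off_axis_err <- 0.02
  d3 <- dose_deviation(sw, m3, base, grid_spec = spec, baseline_map = bmap)
  expect_gt(d3[["oar_near_max"]], d3[["ctv_mean"]])
})
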