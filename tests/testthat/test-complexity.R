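test_that("hand-computed metric examples", {
  geo <- machine_geometry()

  # two CPs, weights 0.25/0.75, uniform gaps 20/40 mm -> mean gap 35
  mk <- function(gap, w) control_point(w, 0, rep(-gap / 2, 60),
                                       rep(gap / 2, 60), -100, 100, -100, 100)
  bm <- beam(list(mk(20, 0), mk(40, 1)), 100, "sliding-window", geo)
  # half-interval weights on cum = (0, 1) give 0.5/0.5; rebuild with the
  # target weights via cumulative fractions 0 -> 0.5 at an inserted midpoint
  bm2 <- beam(list(mk(20, 0), mk(20, 0.25), mk(40, 0.25), mk(40, 1)),
              100, "sliding-window", geo)
  gm <- gap_metrics(bm2)
  # weights: cp1 .125, cp2 .125, cp3 .375, cp4 .375 -> mean 0.25*20+0.75*40
  expect_equal(gm$mean_gap, 35)

  # TGi single CP: bank A (-10,-15), bank B (10,15), gaps 20/30 -> 0.2
  A <- rep(-200, 60); B <- rep(-200, 60)
  A[30] <- -10; B[30] <- 10
  A[31] <- -15; B[31] <- 15
  cp <- control_point(1, 0, A, B, -100, 100, -12.5, 12.5)
  bmt <- beam(list(cp), 10, "static-IMRT", geo)
  expect_equal(tgi(bmt), 0.2)

  # edge metric: two adjacent 5 mm pairs offset by 5 mm, gaps 20/20
  # jaw y restricted to exactly those two pairs (central rows)
  A2 <- rep(-200, 60); B2 <- rep(-200, 60)
  A2[30] <- -10; B2[30] <- 10
  A2[31] <- -5; B2[31] <- 15
  cp2 <- control_point(1, 0, A2, B2, -100, 100, -5, 5)
  bme <- beam(list(cp2), 10, "static-IMRT", geo)
  expect_equal(edge_metric(bme), 2 * 5 / 200)

  # plan irregularity closed form for a w x h rectangle
  p <- make_static_field(20, 50, 10)
  ai <- plan_irregularity(p$beams[[1]])
  expect_equal(ai, (2 * (20 + 50))^2 / (4 * pi * 20 * 50))

  # interdigitation: one junction of 59 with all pairs active
  A3 <- rep(-15, 60); B3 <- rep(15, 60)
  A3[10] <- 5; B3[10] <- 25
  B3[9] <- 2   # pair 9: [-15, 2], pair 10: [5, 25] -> A3[10] > B3[9]
  cp3 <- control_point(1, 0, A3, B3, -100, 100, -250, 250)
  bmi <- beam(list(cp3), 10, "static-IMRT", geo)
  expect_equal(interdigitation_fraction(bmi), 1 / 59)
})

test_that("plan modulation: two equal-MU disjoint equal-area apertures = 0.5", {
  geo <- machine_geometry()
  mk <- function(x0, w) {
    A <- rep(-200, 60); B <- rep(-200, 60)
    A[26:35] <- x0; B[26:35] <- x0 + 20
    control_point(w, 0, A, B, -100, 100, -25, 25)
  }
  # static segments: aperture 1 over MU [0, .5], aperture 2 over [.5, 1]
  bm <- beam(list(mk(-40, 0), mk(-40, 0.5), mk(20, 0.5), mk(20, 1)),
             100, "static-IMRT", geo)
  expect_equal(plan_modulation(bm), 0.5)
})

test_that("dynamics metrics: constant-speed sweep", {
  sw <- make_sliding_window(20, 100, 41, 100, 200)
  bm <- sw$beams[[1]]
  dyn <- dynamics_metrics(bm)
  kin <- oracle_dynamics(bm)
  expect_equal(dyn$mean_mlc_speed, kin$mean_mlc_speed, tolerance = 1e-9)
  # uniform MU fractions and uniform steps -> constant speed, zero modulation
  expect_lt(dyn$mlc_speed_modulation, 1e-9)
  expect_lt(dyn$gantry_speed_modulation, 1e-9)
  expect_identical(modulation_index_total(bm), 0)
})

test_that("all 18 metrics match the naive-loop oracles on seeded plans", {
  plans <- probe_plans(10)
  for (p in plans) {
    for (bm in p$beams) {
      expect_equal(gap_metrics(bm)$mean_gap, oracle_mean_gap(bm),
                   tolerance = 1e-9)
      expect_equal(gap_metrics(bm)$q1_gap, oracle_q1_gap(bm),
                   tolerance = 1e-9)
      expect_equal(tgi(bm), oracle_tgi(bm), tolerance = 1e-9)
      expect_equal(mcs(bm), oracle_mcs(bm), tolerance = 1e-9)
      expect_equal(plan_irregularity(bm), oracle_plan_irregularity(bm),
                   tolerance = 1e-9)
      expect_equal(edge_metric(bm), oracle_edge_metric(bm), tolerance = 1e-9)
      expect_equal(plan_modulation(bm), oracle_plan_modulation(bm),
                   tolerance = 1e-9)
      expect_equal(lt_per_al(bm), oracle_lt_per_al(bm), tolerance = 1e-9)
      expect_equal(interdigitation_fraction(bm), oracle_interdigitation(bm),
                   tolerance = 1e-9)
      expect_equal(modulation_index_total(bm), oracle_mi_total(bm),
                   tolerance = 1e-9)
      kin <- oracle_dynamics(bm)
      if (!is.null(kin)) {
        dyn <- dynamics_metrics(bm)
        for (nm in names(kin))
          expect_equal(dyn[[nm]], kin[[nm]], tolerance = 1e-9, label = nm)
      }
    }
  }
})

test_that("beam averaging: identical beams equal a single beam", {
  p <- generate_plan(probe_presets()[[1]], 21)
  single <- plan_metrics(p)
  doubled <- p
  doubled$beams <- c(p$beams, p$beams)
  both <- plan_metrics(doubled)
  for (nm in setdiff(metric_names(), c("total_mu", "n_arcs")))
    expect_equal(both[[nm]], single[[nm]], tolerance = 1e-12, label = nm)
  expect_equal(both$total_mu, 2 * single$total_mu)
  expect_equal(both$n_arcs, 2 * single$n_arcs)
})

test_that("CP refinement changes mean gap, TGi and MCS by < 1%", {
  # Smooth modulated beam (sinusoidal per-pair trajectories): refinement by
  # linear interpolation must be faithful. (Rough random-walk trajectories
  # are not refinement-invariant by construction - see the methods vignette.)
  geo <- machine_geometry()
  set.seed(9)
  phi <- runif(60, 0, 2 * pi)
  psi <- runif(60, 0, 2 * pi)
  ncp <- 31
  cps <- lapply(seq_len(ncp), function(k) {
    t <- (k - 1) / (ncp - 1)
    ctr <- 12 * sin(2 * pi * t + phi)
    gap <- 18 + 6 * sin(3 * pi * t + psi)
    control_point(t, t * 340, ctr - gap / 2, ctr + gap / 2,
                  -60, 60, -60, 60, nominal_time = t * 60, dose_rate = 300)
  })
  bm <- beam(cps, total_mu = 300, technique = "VMAT-arc", machine = geo,
             arc_span = 340)
  fine <- refine_beam(bm)
  expect_lt(abs(gap_metrics(fine)$mean_gap / gap_metrics(bm)$mean_gap - 1),
            0.01)
  expect_lt(abs(tgi(fine) / tgi(bm) - 1), 0.01)
  expect_lt(abs(mcs(fine) / mcs(bm) - 1), 0.01)
})

test_that("MU scaling leaves aperture metrics unchanged and scales total_mu", {
  p <- generate_plan(probe_presets()[[1]], 41)
  scaled <- p
  scaled$beams <- lapply(p$beams, function(bm) {
    bm$total_mu <- bm$total_mu * 3
    # delivery-consistent scaling: dose rate triples at fixed times
    bm$control_points <- lapply(bm$control_points, function(cp) {
      cp$dose_rate <- cp$dose_rate * 3
      cp
    })
    bm
  })
  m0 <- plan_metrics(p)
  m1 <- plan_metrics(scaled)
  expect_equal(m1$total_mu, 3 * m0$total_mu)
  for (nm in c("mcs", "tgi", "mean_gap", "q1_gap", "plan_irregularity",
               "plan_modulation", "edge_metric", "lt_per_al",
               "interdigitation_fraction", "mean_mlc_speed",
               "mean_gantry_speed", "n_arcs"))
    expect_equal(m1[[nm]], m0[[nm]], label = nm)
  expect_equal(m1$mean_dose_rate, 3 * m0$mean_dose_rate)
})

test_that("metrics with no qualifying input report NA markers", {
  geo <- machine_geometry()
  # all pairs parked closed
  cp <- control_point(1, 0, rep(-190, 60), rep(-190, 60), -10, 10, -10, 10)
  bm <- beam(list(cp), 10, "static-IMRT", geo)
  expect_true(is.na(gap_metrics(bm)$mean_gap))
  expect_true(is.na(tgi(bm)))
  expect_true(is.na(mcs(bm)))
  # < 3 CPs for the modulation index
  sw <- make_sliding_window(20, 80, 2, 100, 100)
  expect_true(is.na(modulation_index_total(sw$beams[[1]])))
})
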