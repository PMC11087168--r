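# Synthetic plan / cohort generation. The generator emulates the statistical
# structure of a 25-plan, 5-site IMRT/VMAT cohort: per-site presets control
# aperture size (hence mean MLC gap), adjacent-leaf decorrelation (hence
# tongue-and-groove index), sweep extent, control-point counts and MU. Site
# ordering of median complexity is head-and-neck ~ mesothelioma (most
# complex, smallest gaps) < prostate < brain ~ lung (least complex).

.MAX_DOSE_RATE <- 600    # MU/min
.MAX_GANTRY_SPEED <- 6   # deg/s
.MAX_LEAF_SPEED <- 25    # mm/s

#' Define a site preset for the synthetic generator
#'
#' @param site_label Anatomical site label.
#' @param technique Delivery technique for the preset.
#' @param n_beams Number of beams (arcs for VMAT).
#' @param cp_count Control points per arc, or segments per static beam.
#' @param target_mean_gap_range Two-element range (mm) from which the
#'   plan-level mean-MLC-gap target is drawn.
#' @param target_tgi_range Descriptive range of the tongue-and-groove index
#'   the preset produces (dimensionless, in `[0, 1)`).
#' @param sweep_extent Lateral extent (mm) available to the aperture sweep.
#' @param field_length Field extent (mm) along the leaf-orthogonal axis.
#' @param mu_range Two-element range of MU per beam.
#' @param adjacency_roughness In `[0, 1]`: 0 = adjacent pairs move together
#'   (smooth apertures, low TGi), 1 = independent pairs (ragged, high TGi).
#' @param gap_dispersion Log-normal sigma of per-pair/per-CP gap noise.
#' @param arc_span Arc length in degrees (VMAT only).
#' @param ctv_depth,oar_depth Nominal readout depths (cm) for the ROIs.
#' @return A `site_preset` list.
#' @export
site_preset <- function(site_label, technique, n_beams, cp_count,
                        target_mean_gap_range, target_tgi_range,
                        sweep_extent, field_length, mu_range,
                        adjacency_roughness, gap_dispersion,
                        arc_span = 340, ctv_depth = 10, oar_depth = 10) {
  stopifnot(all(target_mean_gap_range > 0), diff(target_mean_gap_range) >= 0,
            all(target_tgi_range >= 0), all(target_tgi_range < 1),
            sweep_extent > 0, field_length > 0, all(mu_range > 0),
            adjacency_roughness >= 0, adjacency_roughness <= 1,
            gap_dispersion >= 0)
  structure(list(site_label = site_label, technique = technique,
                 n_beams = n_beams, cp_count = cp_count,
                 target_mean_gap_range = target_mean_gap_range,
                 target_tgi_range = target_tgi_range,
                 sweep_extent = sweep_extent, field_length = field_length,
                 mu_range = mu_range,
                 adjacency_roughness = adjacency_roughness,
                 gap_dispersion = gap_dispersion, arc_span = arc_span,
                 ctv_depth = ctv_depth, oar_depth = oar_depth),
            class = "site_preset")
}

#' Default presets for the five anatomical sites
#'
#' Gap-target ranges bracket the published decision thresholds (20/34 mm) so
#' that threshold derivation is exercised on both sides; head-and-neck and
#' mesothelioma are the most complex (smallest gaps, highest TGi), lung and
#' brain the least.
#'
#' @return Named list of [site_preset()] objects.
#' @export
default_site_presets <- function() {
  list(
    head_and_neck = site_preset("head_and_neck", "VMAT-arc", 2, 36,
                                c(10, 20), c(0.50, 0.95), 100, 120,
                                c(250, 350), 0.80, 0.35, ctv_depth = 6,
                                oar_depth = 5),
    mesothelioma = site_preset("mesothelioma", "static-IMRT", 5, 10,
                               c(12, 22), c(0.45, 0.95), 120, 160,
                               c(60, 100), 0.70, 0.35, ctv_depth = 8,
                               oar_depth = 7),
    prostate = site_preset("prostate", "VMAT-arc", 2, 36,
                           c(18, 32), c(0.20, 0.60), 90, 90,
                           c(300, 400), 0.45, 0.25, ctv_depth = 12,
                           oar_depth = 11),
    brain = site_preset("brain", "VMAT-arc", 1, 48,
                        c(25, 42), c(0.07, 0.35), 90, 80,
                        c(200, 300), 0.30, 0.20, ctv_depth = 7,
                        oar_depth = 6),
    lung = site_preset("lung", "VMAT-arc", 1, 48,
                       c(25, 48), c(0.05, 0.30), 100, 90,
                       c(200, 300), 0.25, 0.20, ctv_depth = 8,
                       oar_depth = 7)
  )
}

#' Cohort specification
#'
#' @param plans_per_site Plans generated per site (default 5, giving the
#'   standard 25-plan cohort over the five default sites).
#' @param sites List of [site_preset()]s.
#' @param master_seed Integer master seed; per-plan seeds are derived from it
#'   with a splittable counter scheme, so cohorts are reproducible
#'   independently of generation order.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(plans_per_site = 5, sites = default_site_presets(),
                        master_seed = 20240314) {
  stopifnot(plans_per_site >= 1)
  structure(list(plans_per_site = as.integer(plans_per_site), sites = sites,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# Splittable child seed: deterministic in (master, index), always < 2^31.
child_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 2147483647 * 48271 +
                index * 99991) %% 2147483629) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Assign nominal times and dose rates so that machine limits (dose rate,
# gantry speed, leaf speed) are respected; dose_rate[i] is the mean rate over
# the interval ending at CP i, with dose_rate[1] mirroring dose_rate[2].
assign_dynamics <- function(cps, total_mu, static = FALSE) {
  n <- length(cps)
  if (n == 1) {
    cps[[1]]$nominal_time <- 0
    cps[[1]]$dose_rate <- .MAX_DOSE_RATE
    return(cps)
  }
  t <- numeric(n)
  dr <- numeric(n)
  for (i in 2:n) {
    dmu <- (cps[[i]]$cumulative_mu_fraction -
              cps[[i - 1]]$cumulative_mu_fraction) * total_mu
    dang <- abs(cps[[i]]$gantry_angle - cps[[i - 1]]$gantry_angle)
    dx <- max(abs(cps[[i]]$bank_A - cps[[i - 1]]$bank_A),
              abs(cps[[i]]$bank_B - cps[[i - 1]]$bank_B))
    dt <- if (static) {
      # segment reshaping is instantaneous by convention (zero-MU interval)
      if (dmu > 0) dmu / .MAX_DOSE_RATE * 60 else 0
    } else {
      max(dmu / .MAX_DOSE_RATE * 60, dang / .MAX_GANTRY_SPEED,
          dx / .MAX_LEAF_SPEED)
    }
    t[i] <- t[i - 1] + dt
    dr[i] <- if (dt > 0) dmu / dt * 60 else 0
  }
  dr[1] <- dr[2]
  for (i in seq_len(n)) {
    cps[[i]]$nominal_time <- t[i]
    cps[[i]]$dose_rate <- dr[i]
  }
  cps
}

field_pairs <- function(machine, field_length) {
  lo <- machine$leaf_boundaries[-length(machine$leaf_boundaries)]
  hi <- machine$leaf_boundaries[-1]
  which(hi > -field_length / 2 + 1e-9 & lo < field_length / 2 - 1e-9)
}

#' Create a single-aperture rectangular static field
#'
#' All leaf pairs inside `field_length` open symmetrically to `gap`; other
#' pairs park closed behind the y-jaws. The beam carries two control points
#' (weights 0 and 1) per the static convention.
#'
#' @param gap Leaf-pair opening (mm), > 0.
#' @param field_length Open field extent (mm) along the leaf axis.
#' @param mu Beam monitor units.
#' @param machine A [machine_geometry()].
#' @return An [rt_plan()] with one static beam.
#' @export
#' @examples
#' p <- make_static_field(30, 100, 100)
#' plan_metrics(p)$mean_gap   # 30
make_static_field <- function(gap, field_length, mu,
                              machine = machine_geometry()) {
  stopifnot(gap > 0)
  if (gap > 2 * machine$max_leaf_position)
    stop("gap exceeds maximum field width")
  np <- machine$leaf_pair_count
  open <- field_pairs(machine, field_length)
  A <- rep(-0.0, np); B <- rep(0.0, np)
  A[open] <- -gap / 2; B[open] <- gap / 2
  # y-jaws sit 8 mm beyond the open field so a parked-leaf (transmission
  # only) region exists inside the jaw window for OAR readouts
  jaw <- list(x1 = -gap / 2 - 5, x2 = gap / 2 + 5,
              y1 = -field_length / 2 - 8, y2 = field_length / 2 + 8)
  mk <- function(w) control_point(w, 0, A, B, jaw$x1, jaw$x2, jaw$y1, jaw$y2)
  cps <- assign_dynamics(list(mk(0), mk(1)), mu, static = TRUE)
  bm <- beam(cps, total_mu = mu, technique = "static-IMRT", machine = machine,
             arc_span = 0)
  m <- min(3, gap / 4)
  rt_plan("static-field", "other", list(bm),
          rois = default_rois(jaw_x = c(jaw$x1, jaw$x2),
                              jaw_y = c(jaw$y1, jaw$y2),
                              ctv_x = c(-gap / 2 + m, gap / 2 - m),
                              ctv_y = c(-field_length / 2 + 5,
                                        field_length / 2 - 5)))
}

#' Create a constant-gap sliding-window beam
#'
#' Every active pair shares identical left/right trajectories sweeping a
#' constant-gap window across `[-sweep/2, +sweep/2]` with uniform MU
#' fractions: the analytic fixture behind the first-order offset law
#' (mean-dose deviation = 2*delta-offset/gap).
#'
#' @param gap Window gap (mm).
#' @param sweep Total tip travel (mm); must exceed `gap`.
#' @param n_cp Number of control points (>= 2).
#' @param field_length Open field extent (mm) along the leaf axis.
#' @param mu Beam monitor units.
#' @param machine A [machine_geometry()].
#' @return An [rt_plan()] with one sliding-window beam.
#' @export
make_sliding_window <- function(gap, sweep, n_cp, field_length, mu,
                                machine = machine_geometry()) {
  stopifnot(n_cp >= 2, gap > 0)
  if (sweep <= gap) stop("sweep must exceed gap (no sweep)")
  np <- machine$leaf_pair_count
  open <- field_pairs(machine, field_length)
  # leading (B) tip travels from -sweep/2+gap to sweep/2; trailing (A) tip
  # from -sweep/2 to sweep/2-gap: the window interior sees uniform exposure
  frac <- seq(0, 1, length.out = n_cp)
  jx <- c(-sweep / 2 - 5, sweep / 2 + 5)
  jy <- c(-field_length / 2 - 8, field_length / 2 + 8)
  cps <- lapply(seq_len(n_cp), function(i) {
    a <- -sweep / 2 + frac[i] * (sweep - gap)
    A <- rep(0.0, np); B <- rep(0.0, np)
    A[open] <- a; B[open] <- a + gap
    control_point(frac[i], 0, A, B, jx[1], jx[2], jy[1], jy[2])
  })
  cps <- assign_dynamics(cps, mu)
  bm <- beam(cps, total_mu = mu, technique = "sliding-window",
             machine = machine, arc_span = 0)
  # CTV spans the uniform-exposure plateau: |x| < sweep/2 - gap (with margin
  # for offset perturbations), so the analytic 2*d-offset/gap law is exact
  ctv_hi <- sweep / 2 - gap - 3
  ctv_x <- if (ctv_hi > 2) c(-ctv_hi, ctv_hi) else c(-1, 1)
  rt_plan("sliding-window", "other", list(bm),
          rois = default_rois(jaw_x = jx, jaw_y = jy, ctv_x = ctv_x))
}

# Smooth reflected random walk of length n within [-half, half].
reflected_walk <- function(n, half, step_sd, start = NULL) {
  if (is.null(start)) start <- runif(1, -half / 2, half / 2)
  x <- cumsum(c(start, rnorm(n - 1, 0, step_sd)))
  if (half <= 0) return(rep(0, n))
  # reflect into [-half, half]
  z <- (x + half) %% (4 * half)
  ifelse(z > 2 * half, 3 * half - z, z - half)
}

#' Generate one synthetic plan from a site preset
#'
#' Per-pair leaf trajectories are smooth random walks: aperture centers mix a
#' shared beam-level walk with per-pair walks (mixing set by
#' `adjacency_roughness`, which therefore controls the tongue-and-groove
#' index), per-CP gaps are log-normal around a plan-level target drawn from
#' `target_mean_gap_range`, MU fractions come from a Dirichlet draw, and
#' times/dose rates respect machine limits. The plan is calibrated so its
#' mean MLC gap lands within 2% of the drawn target.
#'
#' @param preset A [site_preset()].
#' @param seed Integer seed; identical seeds give identical plans.
#' @param plan_id Optional identifier.
#' @param machine A [machine_geometry()].
#' @return An [rt_plan()] that passes [validate_plan()].
#' @export
generate_plan <- function(preset, seed, plan_id = NULL,
                          machine = machine_geometry()) {
  gmin <- min(preset$target_mean_gap_range)
  if (gmin > preset$sweep_extent)
    stop("infeasible preset: gap target exceeds sweep extent")
  if (is.null(plan_id))
    plan_id <- sprintf("%s-%06d", preset$site_label, seed %% 1000000L)
  static <- preset$technique == "static-IMRT"
  with_seed(seed, {
    g_target <- runif(1, preset$target_mean_gap_range[1],
                      preset$target_mean_gap_range[2])
    open <- field_pairs(machine, preset$field_length)
    np <- machine$leaf_pair_count
    half_c <- pmax((preset$sweep_extent - g_target) / 2, 1)
    rho <- preset$adjacency_roughness
    n_beams <- preset$n_beams
    beams <- vector("list", n_beams)
    beam_angles0 <- if (static) seq(0, 360 - 1e-6, by = 360 / n_beams)
                    else rep(20, n_beams)
    for (bi in seq_len(n_beams)) {
      ncp <- preset$cp_count
      step_sd <- half_c / sqrt(ncp) * 1.6
      shared <- reflected_walk(ncp, half_c, step_sd)
      centers <- sapply(open, function(i) {
        own <- reflected_walk(ncp, half_c, step_sd)
        (1 - rho) * shared + rho * own
      })  # ncp x n_open
      lsig <- preset$gap_dispersion
      lz <- matrix(rnorm(ncp * length(open)), ncp)
      # AR(1)-smooth the gap noise along CPs so trajectories stay deliverable
      if (ncp > 1) for (k in 2:ncp) lz[k, ] <- 0.7 * lz[k - 1, ] + 0.3 * lz[k, ]
      gaps <- g_target * exp(lsig * lz - lsig^2 / 2)
      mu <- runif(1, preset$mu_range[1], preset$mu_range[2])
      # Dirichlet MU fractions: one per interval (VMAT) or per segment (static)
      dir <- rgamma(if (static) ncp else ncp - 1, shape = 5)
      cum <- c(0, cumsum(dir) / sum(dir))
      angles <- if (static) rep(beam_angles0[bi], ncp)
                else beam_angles0[bi] + seq(0, preset$arc_span,
                                            length.out = ncp)
      half_sweep <- preset$sweep_extent / 2
      xpark <- -min(half_sweep + 20, machine$max_leaf_position - 5)
      mkcp <- function(k, w, ang) {
        A <- rep(xpark, np); B <- rep(xpark, np)
        a <- centers[k, ] - gaps[k, ] / 2
        b <- centers[k, ] + gaps[k, ] / 2
        a <- pmax(pmin(a, half_sweep - 0.5), -half_sweep)
        b <- pmin(pmax(b, a), half_sweep)
        A[open] <- a; B[open] <- b
        control_point(w, ang, A, B,
                      jaw_x1 = -half_sweep - 10, jaw_x2 = half_sweep + 10,
                      jaw_y1 = -preset$field_length / 2 - 8,
                      jaw_y2 = preset$field_length / 2 + 8)
      }
      if (static) {
        # each segment appears as a start/end CP pair: aperture constant
        # while its MU fraction is delivered, reshaping between segments
        cps <- vector("list", 2 * ncp)
        for (k in seq_len(ncp)) {
          cps[[2 * k - 1]] <- mkcp(k, cum[k], angles[k])
          cps[[2 * k]] <- mkcp(k, cum[k + 1], angles[k])
        }
      } else {
        cps <- lapply(seq_len(ncp), function(k) mkcp(k, cum[k], angles[k]))
      }
      cps <- assign_dynamics(cps, mu, static = static)
      beams[[bi]] <- beam(cps, total_mu = mu, technique = preset$technique,
                          machine = machine,
                          arc_span = if (static) 0 else preset$arc_span)
    }
    plan <- rt_plan(plan_id, preset$site_label, beams,
                    rois = preset_rois(preset))
    calibrate_to_targets(plan, g_target, tol = 0.02)
  })
}

#' Rescale a plan's MLC gaps to hit a mean-gap target
#'
#' Gap widths are rescaled about their aperture centers (MU weights and
#' centers preserved) until the plan mean MLC gap is within `tol` of
#' `target_mean_gap`; at most 20 iterations.
#'
#' @param plan An [rt_plan()].
#' @param target_mean_gap Target mean MLC gap (mm).
#' @param tol Relative tolerance (fraction).
#' @return The calibrated plan.
#' @export
calibrate_to_targets <- function(plan, target_mean_gap, tol = 0.02) {
  current <- plan_metrics(plan)$mean_gap
  if (!is.finite(current)) stop("plan has no active pairs; cannot calibrate")
  best <- plan; best_val <- current
  for (it in seq_len(20)) {
    if (abs(current - target_mean_gap) / target_mean_gap <= tol) return(plan)
    s <- target_mean_gap / current
    plan$beams <- lapply(plan$beams, function(bm) {
      bm$control_points <- lapply(bm$control_points, function(cp) {
        ctr <- (cp$bank_A + cp$bank_B) / 2
        g <- (cp$bank_B - cp$bank_A) * s
        a <- ctr - g / 2
        b <- ctr + g / 2
        lim <- bm$machine$max_leaf_position
        cp$bank_A <- pmax(pmin(a, lim), -lim)
        cp$bank_B <- pmin(pmax(b, cp$bank_A), lim)
        cp
      })
      bm
    })
    current <- plan_metrics(plan)$mean_gap
    if (abs(current - target_mean_gap) < abs(best_val - target_mean_gap)) {
      best <- plan; best_val <- current
    }
  }
  if (abs(best_val - target_mean_gap) / target_mean_gap <= tol) return(best)
  stop(sprintf("calibration did not converge: best mean gap %.3f vs target %.3f",
               best_val, target_mean_gap))
}

#' Generate a synthetic cohort
#'
#' `plans_per_site * length(sites)` plans with per-plan seeds derived
#' deterministically from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @return List of [rt_plan()] objects with unique `plan_id`s.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(plans_per_site = 1))
#' length(cohort)  # 5
generate_cohort <- function(spec) {
  idx <- 0L
  plans <- list()
  for (preset in spec$sites) {
    for (k in seq_len(spec$plans_per_site)) {
      idx <- idx + 1L
      seed <- child_seed(spec$master_seed, idx)
      pid <- sprintf("%s-%02d", preset$site_label, k)
      plans[[idx]] <- generate_plan(preset, seed, plan_id = pid)
    }
  }
  plans
}
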