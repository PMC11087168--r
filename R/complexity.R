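# The 18 plan complexity metrics. All control-point averages are MU-weighted
# (half-interval weights on the cumulative meterset) and run over "active"
# leaf pairs only: gap above the machine's minimum dynamic gap and y-extent
# inside the jaw window. Junction-based metrics (TGi, edge metric,
# interdigitation) consider junctions whose two adjacent pairs are BOTH
# active; a junction against a parked pair lies behind the jaws. Metrics that
# are undefined for a beam (no active pairs, too few control points) are
# reported as NA, never silently 0.

#' Names of the 18 complexity metrics
#' @return Character vector of metric column names, in canonical order.
#' @export
metric_names <- function() {
  c("mcs", "mi_total", "plan_irregularity", "plan_modulation", "edge_metric",
    "lt_per_al", "tgi", "interdigitation_fraction", "mean_mlc_speed",
    "mlc_speed_modulation", "mean_dose_rate", "dose_rate_modulation",
    "mean_gantry_speed", "gantry_speed_modulation", "mean_gap", "q1_gap",
    "total_mu", "n_arcs")
}

# Weighted quantile with linear interpolation between order statistics.
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  pos <- (cw - w / 2) / sum(w)
  if (p <= pos[1]) return(x[1])
  if (p >= pos[length(pos)]) return(x[length(x)])
  stats::approx(pos, x, xout = p, ties = "ordered")$y
}

weighted_sd <- function(x, w) {
  m <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

# Precompute per-beam arrays used by every metric: bank matrices
# (pairs x CPs), gaps, active mask, MU weights, jaw-clipped open intervals
# and row heights.
beam_arrays <- function(bm) {
  A <- cp_bank(bm, "bank_A")
  B <- cp_bank(bm, "bank_B")
  ncp <- ncol(A)
  machine <- bm$machine
  lo <- machine$leaf_boundaries[-length(machine$leaf_boundaries)]
  hi <- machine$leaf_boundaries[-1]
  gaps <- B - A
  act <- matrix(FALSE, nrow(A), ncp)
  L <- R <- matrix(0, nrow(A), ncp)   # jaw-clipped open intervals
  h <- matrix(0, nrow(A), ncp)        # jaw-clipped row heights
  for (ci in seq_len(ncp)) {
    cp <- bm$control_points[[ci]]
    act[, ci] <- active_pairs(cp, machine)
    L[, ci] <- pmax(A[, ci], cp$jaw_x1)
    R[, ci] <- pmin(B[, ci], cp$jaw_x2)
    h[, ci] <- pmax(0, pmin(hi, cp$jaw_y2) - pmax(lo, cp$jaw_y1))
  }
  list(A = A, B = B, gaps = gaps, act = act, L = L, R = R, h = h,
       w = cp_mu_weights(bm), ncp = ncp,
       cum = cp_field(bm, "cumulative_mu_fraction"),
       times = cp_field(bm, "nominal_time"),
       angles = cp_field(bm, "gantry_angle"))
}

#' Mean MLC gap and first-quartile gap of a beam
#'
#' The mean gap is the average leaf-pair opening over active pairs at each
#' control point, weighted by the control point's MU fraction. The
#' first-quartile gap is the 25th percentile of the MU-weighted distribution
#' of individual active gaps (linear interpolation).
#'
#' @param bm A [beam()].
#' @return Named list with `mean_gap` and `q1_gap` (mm); both `NA` when the
#'   beam has no active pairs.
#' @export
gap_metrics <- function(bm) {
  ba <- beam_arrays(bm)
  per_cp <- vapply(seq_len(ba$ncp), function(ci) {
    a <- ba$act[, ci]
    if (!any(a)) NA_real_ else mean(ba$gaps[a, ci])
  }, numeric(1))
  ok <- !is.na(per_cp)
  if (!any(ok)) return(list(mean_gap = NA_real_, q1_gap = NA_real_))
  w <- ba$w[ok] / sum(ba$w[ok])
  mean_gap <- sum(w * per_cp[ok])
  gs <- unlist(lapply(which(ok), function(ci) ba$gaps[ba$act[, ci], ci]))
  ws <- unlist(lapply(which(ok), function(ci) rep(ba$w[ci], sum(ba$act[, ci]))))
  list(mean_gap = mean_gap, q1_gap = weighted_quantile(gs, ws, 0.25))
}

#' Tongue-and-groove index of a beam
#'
#' For each control point, bank, and junction between adjacent active pairs
#' (i, i+1), the ratio `min(1, |x_i - x_{i+1}| / max(eps, (g_i + g_{i+1})/2))`
#' measures how far adjacent leaf ends are staggered relative to the local
#' gap; the index is the MU-weighted mean of these ratios over junctions,
#' banks and control points. 0 for a flat-edged aperture, towards 1 for
#' highly staggered edges.
#'
#' @param bm A [beam()].
#' @param eps Gap floor (mm) guarding the denominator.
#' @return Dimensionless value in `[0, 1]`, or `NA` when no control point has
#'   two adjacent active pairs.
#' @export
tgi <- function(bm, eps = 0.1) {
  ba <- beam_arrays(bm)
  per_cp <- vapply(seq_len(ba$ncp), function(ci) {
    a <- ba$act[, ci]
    j <- which(a[-length(a)] & a[-1])       # junctions, both pairs active
    if (!length(j)) return(NA_real_)
    den <- pmax(eps, (ba$gaps[j, ci] + ba$gaps[j + 1, ci]) / 2)
    rA <- pmin(1, abs(ba$A[j, ci] - ba$A[j + 1, ci]) / den)
    rB <- pmin(1, abs(ba$B[j, ci] - ba$B[j + 1, ci]) / den)
    mean(c(rA, rB))
  }, numeric(1))
  ok <- !is.na(per_cp)
  if (!any(ok)) return(NA_real_)
  sum(ba$w[ok] * per_cp[ok]) / sum(ba$w[ok])
}

#' Modulation complexity score of a beam
#'
#' MCS = sum over control points of MU weight x aperture-area variability x
#' leaf-sequence variability. The aperture-area variability (AAV) is the
#' aperture area divided by the area of the per-leaf maximal aperture over
#' the beam; the leaf-sequence variability (LSV) is the product over banks of
#' `sum(pos_max - |x_i - x_{i+1}|) / ((N-1) * pos_max)` over adjacent active
#' pairs, with `pos_max` the bank's position range at that control point
#' (bank A negated so that larger means more open). 1 for a static
#' rectangle; decreases with modulation. Clipped to `[0, 1]`.
#'
#' @param bm A [beam()].
#' @return Dimensionless value in `[0, 1]` or `NA`.
#' @export
mcs <- function(bm) {
  ba <- beam_arrays(bm)
  widths <- bm$machine$leaf_widths
  open_gap <- ifelse(ba$act, ba$gaps, 0)
  max_gap <- apply(open_gap, 1, max)
  denom <- sum(max_gap * widths)
  if (denom <= 0) return(NA_real_)
  lsv_bank <- function(pos) {
    n <- length(pos)
    if (n <= 1) return(1)
    pos_max <- max(pos) - min(pos)
    if (pos_max <= 0) return(1)
    sum(pos_max - abs(diff(pos))) / ((n - 1) * pos_max)
  }
  val <- 0
  for (ci in seq_len(ba$ncp)) {
    a <- ba$act[, ci]
    aav <- sum(ba$gaps[a, ci] * widths[a]) / denom
    lsv <- lsv_bank(-ba$A[a, ci]) * lsv_bank(ba$B[a, ci])
    val <- val + ba$w[ci] * aav * lsv
  }
  min(1, max(0, val))
}

# Aperture geometry of one CP: area, full perimeter, and the exposed
# leaf-side (horizontal) edge length between adjacent open rows. Rows are the
# jaw-clipped open intervals of active pairs; closed/inactive rows are empty.
aperture_geometry <- function(ba, ci) {
  npair <- nrow(ba$A)
  open <- ba$act[, ci] & (ba$R[, ci] - ba$L[, ci] > 0) & (ba$h[, ci] > 0)
  len <- ifelse(open, ba$R[, ci] - ba$L[, ci], 0)
  area <- sum(len * ba$h[, ci])
  # vertical (leaf-end) edges: two sides per open row
  perim <- 2 * sum(ba$h[open, ci])
  side_exposed_both <- 0  # between two open rows: symmetric difference
  caps <- 0               # against closed rows / outer boundaries
  for (i in 0:npair) {
    lo_open <- i >= 1 && open[i]
    hi_open <- i < npair && open[i + 1]
    if (!lo_open && !hi_open) next
    if (lo_open && hi_open) {
      ov <- max(0, min(ba$R[i, ci], ba$R[i + 1, ci]) -
                   max(ba$L[i, ci], ba$L[i + 1, ci]))
      side_exposed_both <- side_exposed_both + len[i] + len[i + 1] - 2 * ov
    } else if (lo_open) {
      caps <- caps + len[i]
    } else {
      caps <- caps + len[i + 1]
    }
  }
  list(area = area, perimeter = perim + side_exposed_both + caps,
       side_exposed = side_exposed_both)
}

#' Plan irregularity of a beam
#'
#' Per control point, the aperture irregularity `AI = P^2 / (4 pi A)` of the
#' rectilinear aperture polygon (leaf steps clipped by the jaws); 1 for a
#' circle, 4/pi for a square, growing with raggedness. The beam value is the
#' MU-weighted mean over control points with non-zero aperture area.
#'
#' @param bm A [beam()].
#' @return Dimensionless value >= 1, or `NA`.
#' @export
plan_irregularity <- function(bm) {
  ba <- beam_arrays(bm)
  per_cp <- vapply(seq_len(ba$ncp), function(ci) {
    g <- aperture_geometry(ba, ci)
    if (g$area <= 0) NA_real_ else g$perimeter^2 / (4 * pi * g$area)
  }, numeric(1))
  ok <- !is.na(per_cp)
  if (!any(ok)) return(NA_real_)
  sum(ba$w[ok] * per_cp[ok]) / sum(ba$w[ok])
}

#' Edge metric of a beam
#'
#' Per control point, the exposed leaf-side edge length inside the aperture
#' (the symmetric difference of adjacent open rows' intervals) divided by the
#' aperture area; MU-weighted mean over control points. Units 1/mm.
#'
#' @param bm A [beam()].
#' @return Edge metric (1/mm) or `NA`.
#' @export
edge_metric <- function(bm) {
  ba <- beam_arrays(bm)
  per_cp <- vapply(seq_len(ba$ncp), function(ci) {
    g <- aperture_geometry(ba, ci)
    if (g$area <= 0) NA_real_ else g$side_exposed / g$area
  }, numeric(1))
  ok <- !is.na(per_cp)
  if (!any(ok)) return(NA_real_)
  sum(ba$w[ok] * per_cp[ok]) / sum(ba$w[ok])
}

#' Plan modulation of a beam
#'
#' `PM = 1 - sum_cp MU_cp * A_cp / (MU_beam * A_union)` where `A_union` is
#' the area of the union of all control-point apertures. 0 for a static
#' single aperture, approaching 1 for heavily modulated beams.
#'
#' @param bm A [beam()].
#' @return Dimensionless value in `[0, 1)` or `NA`.
#' @export
plan_modulation <- function(bm) {
  ba <- beam_arrays(bm)
  areas <- vapply(seq_len(ba$ncp), function(ci) {
    aperture_geometry(ba, ci)$area
  }, numeric(1))
  # per-pair 1D union of open intervals across CPs, times row height
  union_area <- 0
  for (i in seq_len(nrow(ba$A))) {
    cis <- which(ba$act[i, ] & ba$R[i, ] - ba$L[i, ] > 0 & ba$h[i, ] > 0)
    if (!length(cis)) next
    iv <- cbind(ba$L[i, cis], ba$R[i, cis])
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    tot <- 0; cur_l <- iv[1, 1]; cur_r <- iv[1, 2]
    if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
      if (iv[k, 1] > cur_r) {
        tot <- tot + (cur_r - cur_l); cur_l <- iv[k, 1]; cur_r <- iv[k, 2]
      } else cur_r <- max(cur_r, iv[k, 2])
    }
    tot <- tot + (cur_r - cur_l)
    union_area <- union_area + tot * max(ba$h[i, cis])
  }
  if (union_area <= 0) return(NA_real_)
  max(0, 1 - sum(ba$w * areas) / union_area)
}

#' Leaf travel per arc length (or per control point)
#'
#' Mean over ever-active leaves of the total tip travel `sum |dx|`, divided
#' by the gantry arc span for VMAT beams (mm/deg) or by `n_cp - 1` for
#' static-gantry beams (mm/CP).
#'
#' @param bm A [beam()].
#' @return mm/deg (VMAT) or mm/CP, or `NA`.
#' @export
lt_per_al <- function(bm) {
  ba <- beam_arrays(bm)
  if (ba$ncp < 2) return(0)
  ever <- which(rowSums(ba$act) > 0)
  if (!length(ever)) return(NA_real_)
  travel <- c(rowSums(abs(ba$A[ever, , drop = FALSE][, -1, drop = FALSE] -
                            ba$A[ever, , drop = FALSE][, -ba$ncp, drop = FALSE])),
              rowSums(abs(ba$B[ever, , drop = FALSE][, -1, drop = FALSE] -
                            ba$B[ever, , drop = FALSE][, -ba$ncp, drop = FALSE])))
  denom <- if (bm$arc_span > 0) bm$arc_span else (ba$ncp - 1)
  mean(travel) / denom
}

#' MLC interdigitation fraction of a beam
#'
#' Fraction of junctions between adjacent active pairs where one pair's A
#' leaf extends past the neighbouring pair's B leaf
#' (`x_A,i > x_B,i+1` or `x_A,i+1 > x_B,i`); MU-weighted over control points,
#' uniform over junctions.
#'
#' @param bm A [beam()].
#' @return Fraction in `[0, 1]` or `NA`.
#' @export
interdigitation_fraction <- function(bm) {
  ba <- beam_arrays(bm)
  per_cp <- vapply(seq_len(ba$ncp), function(ci) {
    a <- ba$act[, ci]
    j <- which(a[-length(a)] & a[-1])
    if (!length(j)) return(NA_real_)
    inter <- (ba$A[j, ci] > ba$B[j + 1, ci]) | (ba$A[j + 1, ci] > ba$B[j, ci])
    mean(inter)
  }, numeric(1))
  ok <- !is.na(per_cp)
  if (!any(ok)) return(NA_real_)
  sum(ba$w[ok] * per_cp[ok]) / sum(ba$w[ok])
}

# Per-interval kinematics of a dynamic beam: time steps, per-leaf speeds of
# ever-active pairs (both banks), dose rate (MU/min) and gantry speed.
beam_kinematics <- function(bm, ba = beam_arrays(bm)) {
  n <- ba$ncp
  dt <- diff(ba$times)
  if (any(dt <= 0)) stop("malformed plan: non-increasing nominal time in dynamic beam")
  dmu <- diff(ba$cum) * bm$total_mu
  ever <- which(rowSums(ba$act) > 0)
  dA <- abs(ba$A[ever, -1, drop = FALSE] - ba$A[ever, -n, drop = FALSE])
  dB <- abs(ba$B[ever, -1, drop = FALSE] - ba$B[ever, -n, drop = FALSE])
  speeds <- rbind(dA, dB) / matrix(dt, 2 * length(ever), n - 1, byrow = TRUE)
  list(dt = dt, w_int = diff(ba$cum), speeds = speeds,
       dose_rate = dmu / dt * 60, gantry_speed = abs(diff(ba$angles)) / dt)
}

#' Delivery-dynamics metrics of a beam
#'
#' Per control-point interval: leaf speed `|dx|/dt` for each ever-active
#' leaf, dose rate `dMU/dt` and gantry speed `|dangle|/dt`. "Mean" is the
#' MU-weighted mean over intervals (and leaves for the MLC); "modulation" is
#' the MU-weighted standard deviation of the same population. Static beams
#' report zero speeds and modulations by convention.
#'
#' @param bm A [beam()].
#' @return Named list: `mean_mlc_speed`, `mlc_speed_modulation` (mm/s),
#'   `mean_dose_rate`, `dose_rate_modulation` (MU/min), `mean_gantry_speed`,
#'   `gantry_speed_modulation` (deg/s).
#' @export
dynamics_metrics <- function(bm) {
  zero <- list(mean_mlc_speed = 0, mlc_speed_modulation = 0,
               mean_dose_rate = 0, dose_rate_modulation = 0,
               mean_gantry_speed = 0, gantry_speed_modulation = 0)
  if (bm$technique == "static-IMRT") {
    zero$mean_dose_rate <- mean(cp_field(bm, "dose_rate"))
    return(zero)
  }
  ba <- beam_arrays(bm)
  if (ba$ncp < 2) return(zero)
  kin <- beam_kinematics(bm, ba)
  w <- kin$w_int
  if (sum(w) <= 0) return(zero)
  nl <- nrow(kin$speeds)
  wl <- matrix(w, nl, length(w), byrow = TRUE) / nl
  list(
    mean_mlc_speed = sum(wl * kin$speeds) / sum(wl),
    mlc_speed_modulation = weighted_sd(as.vector(kin$speeds), as.vector(wl)),
    mean_dose_rate = sum(w * kin$dose_rate) / sum(w),
    dose_rate_modulation = weighted_sd(kin$dose_rate, w),
    mean_gantry_speed = sum(w * kin$gantry_speed) / sum(w),
    gantry_speed_modulation = weighted_sd(kin$gantry_speed, w)
  )
}

#' Total modulation index of a beam
#'
#' `z(f)` is the weighted fraction of per-leaf speed changes between
#' consecutive intervals exceeding `f` standard deviations of all speed
#' changes; the base index is the trapezoidal integral of `z` over
#' `f in [0, 1]` (100 points). Each counted change is weighted by
#' multiplicative penalties `(1 + |accel|/a_ref) (1 + |d doserate|/dr_ref)
#' (1 + |d gantryspeed|/gs_ref)`, normalized by the weight sum. A
#' constant-speed beam scores 0.
#'
#' @param bm A [beam()].
#' @param a_ref,dr_ref,gs_ref Reference scales for the penalty factors
#'   (mm/s^2, MU/min, deg/s).
#' @return Dimensionless value in `[0, 1]`, or `NA` for beams with fewer
#'   than 3 control points.
#' @export
modulation_index_total <- function(bm, a_ref = 40, dr_ref = 300, gs_ref = 3) {
  ba <- beam_arrays(bm)
  if (ba$ncp < 3) return(NA_real_)
  if (bm$technique == "static-IMRT") return(0)
  kin <- beam_kinematics(bm, ba)
  nint <- length(kin$dt)
  ch <- kin$speeds[, -1, drop = FALSE] - kin$speeds[, -nint, drop = FALSE]
  sigma <- stats::sd(as.vector(ch))
  # guard against floating-point dust on constant-speed beams
  if (!is.finite(sigma) || sigma <= 1e-9 * max(1, max(abs(kin$speeds))))
    return(0)
  dt_mid <- (kin$dt[-1] + kin$dt[-nint]) / 2
  accel <- abs(ch) / matrix(dt_mid, nrow(ch), nint - 1, byrow = TRUE)
  ddr <- abs(diff(kin$dose_rate))
  dgs <- abs(diff(kin$gantry_speed))
  pen_j <- (1 + ddr / dr_ref) * (1 + dgs / gs_ref)
  wts <- (1 + accel / a_ref) * matrix(pen_j, nrow(ch), nint - 1, byrow = TRUE)
  fs <- seq(0, 1, length.out = 100)
  z <- vapply(fs, function(f) sum(wts[abs(ch) > f * sigma]) / sum(wts),
              numeric(1))
  sum((z[-1] + z[-length(z)]) / 2 * diff(fs))
}

# All 18 metrics for one beam, as a named list.
beam_metrics <- function(bm) {
  gm <- gap_metrics(bm)
  dyn <- dynamics_metrics(bm)
  c(list(
    mcs = mcs(bm),
    mi_total = modulation_index_total(bm),
    plan_irregularity = plan_irregularity(bm),
    plan_modulation = plan_modulation(bm),
    edge_metric = edge_metric(bm),
    lt_per_al = lt_per_al(bm),
    tgi = tgi(bm),
    interdigitation_fraction = interdigitation_fraction(bm)
  ), dyn, list(
    mean_gap = gm$mean_gap,
    q1_gap = gm$q1_gap,
    total_mu = bm$total_mu,
    n_arcs = as.numeric(bm$technique == "VMAT-arc")
  ))
}

#' Compute all 18 complexity metrics for a plan
#'
#' Beam-level metrics are combined across beams by MU-weighted mean;
#' `total_mu` and `n_arcs` are summed. Undefined beam metrics (NA) propagate
#' to the plan value. Metrics depend only on the plan, never on any
#' beam-model perturbation applied downstream.
#'
#' @param plan An [rt_plan()].
#' @return Named list (a metric vector) with the 18 entries of
#'   [metric_names()].
#' @export
#' @examples
#' mv <- plan_metrics(make_static_field(30, 100, 100))
#' mv$mcs; mv$tgi; mv$mean_gap
plan_metrics <- function(plan) {
  per_beam <- lapply(plan$beams, beam_metrics)
  mus <- vapply(plan$beams, `[[`, numeric(1), "total_mu")
  wb <- mus / sum(mus)
  out <- stats::setNames(vector("list", length(metric_names())), metric_names())
  for (nm in metric_names()) {
    vals <- vapply(per_beam, function(x) as.numeric(x[[nm]]), numeric(1))
    out[[nm]] <- if (nm %in% c("total_mu", "n_arcs")) sum(vals)
                 else sum(wb * vals)
  }
  out
}
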