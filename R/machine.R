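#' Machine geometry for a 120-leaf Varian Millennium MLC
#'
#' Describes the leaf-pair layout of the collimator: 60 opposed leaf pairs,
#' 10 outer pairs of 10 mm width, 40 central pairs of 5 mm, 10 outer pairs of
#' 10 mm, spanning 400 mm symmetrically about the beam axis. All positions
#' are projected to the isocenter plane and expressed in mm.
#'
#' @param leaf_widths Numeric vector of per-pair physical widths (mm) at
#'   isocenter, ordered along the axis orthogonal to leaf travel. Default is
#'   the Millennium 120 layout.
#' @param max_leaf_position Maximum leaf tip excursion from the axis (mm).
#' @param min_dynamic_gap Gap below which a pair is considered closed for the
#'   purpose of metric averaging (mm).
#'
#' @return An object of class `machine_geometry` with fields
#'   `leaf_pair_count`, `leaf_widths`, `leaf_boundaries` (61 cumulative
#'   y-positions, symmetric about 0), `max_leaf_position`, `min_dynamic_gap`.
#' @export
#' @examples
#' geo <- machine_geometry()
#' geo$leaf_pair_count        # 60
#' range(geo$leaf_boundaries) # -200 200
machine_geometry <- function(leaf_widths = c(rep(10, 10), rep(5, 40), rep(10, 10)),
                             max_leaf_position = 200,
                             min_dynamic_gap = 0.6) {
  stopifnot(all(leaf_widths > 0), max_leaf_position > 0, min_dynamic_gap >= 0)
  span <- sum(leaf_widths)
  boundaries <- cumsum(c(-span / 2, leaf_widths))
  structure(list(
    leaf_pair_count = length(leaf_widths),
    leaf_widths = as.numeric(leaf_widths),
    leaf_boundaries = as.numeric(boundaries),
    max_leaf_position = max_leaf_position,
    min_dynamic_gap = min_dynamic_gap
  ), class = "machine_geometry")
}

#' Construct a control point
#'
#' A control point is a snapshot of machine state during delivery: per-pair
#' leaf tip positions for both banks, jaw settings, gantry angle, cumulative
#' monitor-unit (MU) fraction, elapsed time and dose rate. Bank A is the
#' left/negative bank, bank B the right/positive bank, so the leaf-pair gap
#' is `bank_B - bank_A`.
#'
#' @param cumulative_mu_fraction Cumulative MU fraction in `[0, 1]`.
#' @param gantry_angle Gantry angle, degrees.
#' @param bank_A,bank_B Numeric vectors of per-pair tip x-positions (mm at
#'   isocenter), one element per leaf pair.
#' @param jaw_x1,jaw_x2,jaw_y1,jaw_y2 Jaw positions (mm); x1 <= x2, y1 <= y2.
#' @param nominal_time Seconds from beam start.
#' @param dose_rate Dose rate (MU/min) averaged over the interval ending at
#'   this control point.
#' @return An object of class `control_point`.
#' @export
control_point <- function(cumulative_mu_fraction, gantry_angle, bank_A, bank_B,
                          jaw_x1 = -200, jaw_x2 = 200, jaw_y1 = -200, jaw_y2 = 200,
                          nominal_time = 0, dose_rate = 0) {
  stopifnot(length(bank_A) == length(bank_B))
  structure(list(
    cumulative_mu_fraction = as.numeric(cumulative_mu_fraction),
    gantry_angle = as.numeric(gantry_angle),
    bank_A = as.numeric(bank_A),
    bank_B = as.numeric(bank_B),
    jaw_x1 = as.numeric(jaw_x1), jaw_x2 = as.numeric(jaw_x2),
    jaw_y1 = as.numeric(jaw_y1), jaw_y2 = as.numeric(jaw_y2),
    nominal_time = as.numeric(nominal_time),
    dose_rate = as.numeric(dose_rate)
  ), class = "control_point")
}

#' Construct a beam
#'
#' @param control_points List of [control_point()] objects in delivery order.
#' @param total_mu Total monitor units for the beam (> 0).
#' @param technique One of `"static-IMRT"`, `"sliding-window"`, `"VMAT-arc"`.
#' @param machine A [machine_geometry()] object.
#' @param arc_span Gantry arc length in degrees (0 for static gantry).
#' @return An object of class `beam`.
#' @export
beam <- function(control_points, total_mu,
                 technique = c("VMAT-arc", "sliding-window", "static-IMRT"),
                 machine = machine_geometry(), arc_span = 0) {
  technique <- match.arg(technique)
  structure(list(
    control_points = control_points,
    total_mu = as.numeric(total_mu),
    technique = technique,
    machine = machine,
    arc_span = as.numeric(arc_span)
  ), class = "beam")
}

#' Construct a plan
#'
#' @param plan_id Character plan identifier, unique within a cohort.
#' @param site_label One of `"prostate"`, `"lung"`, `"head_and_neck"`,
#'   `"brain"`, `"mesothelioma"`, `"other"`.
#' @param beams List of [beam()] objects (at least one).
#' @param rois Optional [roi_set()] giving the CTV/OAR readout regions.
#' @return An object of class `rt_plan`.
#' @export
rt_plan <- function(plan_id, site_label, beams, rois = NULL) {
  site_label <- match.arg(site_label, c("prostate", "lung", "head_and_neck",
                                        "brain", "mesothelioma", "other"))
  structure(list(
    plan_id = as.character(plan_id),
    site_label = site_label,
    beams = beams,
    rois = rois
  ), class = "rt_plan")
}

#' @export
print.rt_plan <- function(x, ...) {
  ncp <- vapply(x$beams, function(b) length(b$control_points), integer(1))
  cat(sprintf("<rt_plan> %s  site=%s  beams=%d  CPs=%s  MU=%.1f\n",
              x$plan_id, x$site_label, length(x$beams),
              paste(ncp, collapse = "+"),
              sum(vapply(x$beams, `[[`, numeric(1), "total_mu"))))
  invisible(x)
}

# --- internal helpers shared by metrics and the fluence surrogate ------------

# Logical vector: which leaf pairs are "active" at a CP. A pair is active iff
# its gap exceeds the machine's minimum dynamic gap AND its y-extent overlaps
# the open jaw window. Parked/closed pairs are excluded from all per-leaf
# metric averages.
active_pairs <- function(cp, machine) {
  gaps <- cp$bank_B - cp$bank_A
  lo <- machine$leaf_boundaries[-length(machine$leaf_boundaries)]
  hi <- machine$leaf_boundaries[-1]
  (gaps > machine$min_dynamic_gap) & (hi > cp$jaw_y1) & (lo < cp$jaw_y2)
}

# Per-CP MU weights for a beam: half-interval rule on the cumulative meterset.
# w_i = (cum[i+1] - cum[i-1]) / 2 with the boundary terms taking half
# intervals; for a single CP, w = 1. Weights sum to 1.
cp_mu_weights <- function(bm) {
  cum <- vapply(bm$control_points, `[[`, numeric(1), "cumulative_mu_fraction")
  n <- length(cum)
  if (n == 1L) return(1)
  d <- diff(cum)
  w <- c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
  if (n == 2L) w <- c(d[1] / 2, d[1] / 2)
  w
}

cp_field <- function(bm, field) {
  vapply(bm$control_points, `[[`, numeric(1), field)
}

cp_bank <- function(bm, bank) {
  do.call(cbind, lapply(bm$control_points, `[[`, bank))
}

#' Validate a plan against its structural invariants
#'
#' Checks, without throwing, that leaf banks never cross, cumulative MU is
#' non-decreasing and spans `[0, 1]` per beam, nominal times are
#' non-decreasing, leaf counts match the machine, total MU is positive, leaf
#' tips respect the machine excursion limit, and dynamic beams have at least
#' two control points.
#'
#' @param plan An [rt_plan()].
#' @return A character vector of human-readable violation descriptors; empty
#'   when the plan satisfies every invariant.
#' @export
#' @examples
#' validate_plan(make_static_field(30, 100, 100))  # character(0)
validate_plan <- function(plan) {
  v <- character(0)
  if (length(plan$beams) < 1) v <- c(v, "plan has no beams")
  for (bi in seq_along(plan$beams)) {
    bm <- plan$beams[[bi]]
    tag <- sprintf("beam %d", bi)
    if (!is.finite(bm$total_mu) || bm$total_mu <= 0)
      v <- c(v, sprintf("%s: total_mu not positive", tag))
    ncp <- length(bm$control_points)
    if (bm$technique != "static-IMRT" && ncp < 2)
      v <- c(v, sprintf("%s: dynamic technique with < 2 control points", tag))
    npair <- bm$machine$leaf_pair_count
    cum_prev <- -Inf; t_prev <- -Inf
    for (ci in seq_len(ncp)) {
      cp <- bm$control_points[[ci]]
      if (length(cp$bank_A) != npair || length(cp$bank_B) != npair)
        v <- c(v, sprintf("%s CP %d: leaf count != %d pairs", tag, ci, npair))
      bad <- which(cp$bank_B - cp$bank_A < -1e-9)
      if (length(bad))
        v <- c(v, sprintf("%s CP %d: bank A crosses bank B on pair %s",
                          tag, ci, paste(bad, collapse = ",")))
      out <- which(abs(cp$bank_A) > bm$machine$max_leaf_position + 1e-9 |
                   abs(cp$bank_B) > bm$machine$max_leaf_position + 1e-9)
      if (length(out))
        v <- c(v, sprintf("%s CP %d: leaf beyond max excursion on pair %s",
                          tag, ci, paste(out, collapse = ",")))
      if (cp$cumulative_mu_fraction < cum_prev - 1e-12)
        v <- c(v, sprintf("%s CP %d: decreasing cumulative MU", tag, ci))
      if (cp$nominal_time < t_prev - 1e-9)
        v <- c(v, sprintf("%s CP %d: decreasing nominal time", tag, ci))
      cum_prev <- cp$cumulative_mu_fraction
      t_prev <- cp$nominal_time
    }
    if (ncp >= 1) {
      first <- bm$control_points[[1]]$cumulative_mu_fraction
      last <- bm$control_points[[ncp]]$cumulative_mu_fraction
      if (ncp >= 2 && (abs(first) > 1e-9 || abs(last - 1) > 1e-9))
        v <- c(v, sprintf("%s: cumulative MU fraction does not span [0,1]", tag))
    }
  }
  v
}
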