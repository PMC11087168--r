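# Independent naive-loop reimplementations of every metric, used as oracles.
# Deliberately written as plain double/triple loops over control points and
# leaf pairs, sharing no code with the package internals.

o_weights <- function(bm) {
  cum <- sapply(bm$control_points, function(cp) cp$cumulative_mu_fraction)
  n <- length(cum)
  if (n == 1) return(1)
  w <- numeric(n)
  for (i in seq_len(n)) {
    lo <- if (i == 1) cum[1] else cum[i - 1]
    hi <- if (i == n) cum[n] else cum[i + 1]
    w[i] <- (hi - lo) / 2
  }
  w
}

o_active <- function(cp, machine) {
  out <- logical(machine$leaf_pair_count)
  for (i in seq_len(machine$leaf_pair_count)) {
    g <- cp$bank_B[i] - cp$bank_A[i]
    lo <- machine$leaf_boundaries[i]
    hi <- machine$leaf_boundaries[i + 1]
    out[i] <- g > machine$min_dynamic_gap && hi > cp$jaw_y1 && lo < cp$jaw_y2
  }
  out
}

oracle_mean_gap <- function(bm) {
  w <- o_weights(bm)
  num <- 0; den <- 0
  for (ci in seq_along(bm$control_points)) {
    cp <- bm$control_points[[ci]]
    act <- o_active(cp, bm$machine)
    if (!any(act)) next
    gaps <- (cp$bank_B - cp$bank_A)[act]
    num <- num + w[ci] * mean(gaps)
    den <- den + w[ci]
  }
  if (den == 0) NA_real_ else num / den
}

oracle_q1_gap <- function(bm) {
  w <- o_weights(bm)
  xs <- c(); ws <- c()
  for (ci in seq_along(bm$control_points)) {
    cp <- bm$control_points[[ci]]
    act <- o_active(cp, bm$machine)
    for (i in which(act)) {
      xs <- c(xs, cp$bank_B[i] - cp$bank_A[i])
      ws <- c(ws, w[ci])
    }
  }
  if (!length(xs)) return(NA_real_)
  o <- order(xs); xs <- xs[o]; ws <- ws[o]
  cw <- cumsum(ws)
  pos <- (cw - ws / 2) / sum(ws)
  p <- 0.25
  if (p <= pos[1]) return(xs[1])
  if (p >= pos[length(pos)]) return(xs[length(xs)])
  k <- max(which(pos <= p))
  xs[k] + (xs[k + 1] - xs[k]) * (p - pos[k]) / (pos[k + 1] - pos[k])
}

oracle_tgi <- function(bm, eps = 0.1) {
  w <- o_weights(bm)
  num <- 0; den <- 0
  for (ci in seq_along(bm$control_points)) {
    cp <- bm$control_points[[ci]]
    act <- o_active(cp, bm$machine)
    rs <- c()
    for (i in seq_len(bm$machine$leaf_pair_count - 1)) {
      if (!(act[i] && act[i + 1])) next
      gbar <- max(eps, ((cp$bank_B[i] - cp$bank_A[i]) +
                          (cp$bank_B[i + 1] - cp$bank_A[i + 1])) / 2)
      rs <- c(rs, min(1, abs(cp$bank_A[i] - cp$bank_A[i + 1]) / gbar),
              min(1, abs(cp$bank_B[i] - cp$bank_B[i + 1]) / gbar))
    }
    if (!length(rs)) next
    num <- num + w[ci] * mean(rs)
    den <- den + w[ci]
  }
  if (den == 0) NA_real_ else num / den
}

oracle_mcs <- function(bm) {
  machine <- bm$machine
  widths <- machine$leaf_widths
  maxg <- numeric(machine$leaf_pair_count)
  for (ci in seq_along(bm$control_points)) {
    cp <- bm$control_points[[ci]]
    act <- o_active(cp, machine)
    for (i in which(act))
      maxg[i] <- max(maxg[i], cp$bank_B[i] - cp$bank_A[i])
  }
  denom <- sum(maxg * widths)
  if (denom <= 0) return(NA_real_)
  w <- o_weights(bm)
  lsv1 <- function(pos) {
    if (length(pos) <= 1) return(1)
    pm <- max(pos) - min(pos)
    if (pm <= 0) return(1)
    s <- 0
    for (k in seq_len(length(pos) - 1)) s <- s + pm - abs(pos[k] - pos[k + 1])
    s / ((length(pos) - 1) * pm)
  }
  total <- 0
  for (ci in seq_along(bm$control_points)) {
    cp <- bm$control_points[[ci]]
    act <- o_active(cp, machine)
    aav <- sum((cp$bank_B - cp$bank_A)[act] * widths[act]) / denom
    lsv <- lsv1(-cp$bank_A[act]) * lsv1(cp$bank_B[act])
    total <- total + w[ci] * aav * lsv
  }
  min(1, max(0, total))
}

# rows of the aperture at one CP: jaw-clipped open intervals of active pairs
o_rows <- function(cp, machine) {
  act <- o_active(cp, machine)
  rows <- vector("list", machine$leaf_pair_count)
  for (i in seq_len(machine$leaf_pair_count)) {
    if (!act[i]) next
    l <- max(cp$bank_A[i], cp$jaw_x1)
    r <- min(cp$bank_B[i], cp$jaw_x2)
    lo <- max(machine$leaf_boundaries[i], cp$jaw_y1)
    hi <- min(machine$leaf_boundaries[i + 1], cp$jaw_y2)
    if (r - l <= 0 || hi - lo <= 0) next
    rows[[i]] <- c(l = l, r = r, h = hi - lo)
  }
  rows
}

o_cp_geom <- function(cp, machine) {
  rows <- o_rows(cp, machine)
  area <- 0; perim <- 0; side_both <- 0
  np <- machine$leaf_pair_count
  for (i in seq_len(np)) {
    if (is.null(rows[[i]])) next
    area <- area + (rows[[i]]["r"] - rows[[i]]["l"]) * rows[[i]]["h"]
    perim <- perim + 2 * rows[[i]]["h"]
  }
  for (b in 0:np) {
    lo <- if (b >= 1) rows[[b]] else NULL
    hi <- if (b < np) rows[[b + 1]] else NULL
    if (is.null(lo) && is.null(hi)) next
    if (!is.null(lo) && !is.null(hi)) {
      ov <- max(0, min(lo["r"], hi["r"]) - max(lo["l"], hi["l"]))
      sym <- (lo["r"] - lo["l"]) + (hi["r"] - hi["l"]) - 2 * ov
      perim <- perim + sym
      side_both <- side_both + sym
    } else if (!is.null(lo)) {
      perim <- perim + (lo["r"] - lo["l"])
    } else {
      perim <- perim + (hi["r"] - hi["l"])
    }
  }
  c(area = unname(area), perim = unname(perim), side = unname(side_both))
}

oracle_plan_irregularity <- function(bm) {
  w <- o_weights(bm)
  num <- 0; den <- 0
  for (ci in seq_along(bm$control_points)) {
    g <- o_cp_geom(bm$control_points[[ci]], bm$machine)
    if (g["area"] <= 0) next
    num <- num + w[ci] * unname(g["perim"])^2 / (4 * pi * unname(g["area"]))
    den <- den + w[ci]
  }
  if (den == 0) NA_real_ else num / den
}

oracle_edge_metric <- function(bm) {
  w <- o_weights(bm)
  num <- 0; den <- 0
  for (ci in seq_along(bm$control_points)) {
    g <- o_cp_geom(bm$control_points[[ci]], bm$machine)
    if (g["area"] <= 0) next
    num <- num + w[ci] * unname(g["side"] / g["area"])
    den <- den + w[ci]
  }
  if (den == 0) NA_real_ else num / den
}

oracle_plan_modulation <- function(bm) {
  w <- o_weights(bm)
  wa <- 0
  for (ci in seq_along(bm$control_points))
    wa <- wa + w[ci] * o_cp_geom(bm$control_points[[ci]], bm$machine)["area"]
  union_area <- 0
  np <- bm$machine$leaf_pair_count
  for (i in seq_len(np)) {
    ivs <- list()
    hmax <- 0
    for (ci in seq_along(bm$control_points)) {
      rows <- o_rows(bm$control_points[[ci]], bm$machine)
      if (is.null(rows[[i]])) next
      ivs[[length(ivs) + 1]] <- rows[[i]][c("l", "r")]
      hmax <- max(hmax, rows[[i]]["h"])
    }
    if (!length(ivs)) next
    # naive union by 0.01 mm sampling-free sweep: merge sorted intervals
    m <- do.call(rbind, ivs)
    m <- m[order(m[, 1]), , drop = FALSE]
    tot <- 0; cl <- m[1, 1]; cr <- m[1, 2]
    if (nrow(m) > 1) for (k in 2:nrow(m)) {
      if (m[k, 1] > cr) { tot <- tot + cr - cl; cl <- m[k, 1]; cr <- m[k, 2] }
      else cr <- max(cr, m[k, 2])
    }
    tot <- tot + cr - cl
    union_area <- union_area + tot * hmax
  }
  if (union_area <= 0) return(NA_real_)
  max(0, 1 - unname(wa) / union_area)
}

oracle_lt_per_al <- function(bm) {
  ncp <- length(bm$control_points)
  if (ncp < 2) return(0)
  machine <- bm$machine
  ever <- logical(machine$leaf_pair_count)
  for (ci in seq_len(ncp))
    ever <- ever | o_active(bm$control_points[[ci]], machine)
  if (!any(ever)) return(NA_real_)
  travels <- c()
  for (i in which(ever)) {
    tA <- 0; tB <- 0
    for (ci in 2:ncp) {
      tA <- tA + abs(bm$control_points[[ci]]$bank_A[i] -
                       bm$control_points[[ci - 1]]$bank_A[i])
      tB <- tB + abs(bm$control_points[[ci]]$bank_B[i] -
                       bm$control_points[[ci - 1]]$bank_B[i])
    }
    travels <- c(travels, tA, tB)
  }
  denom <- if (bm$arc_span > 0) bm$arc_span else ncp - 1
  mean(travels) / denom
}

oracle_interdigitation <- function(bm) {
  w <- o_weights(bm)
  num <- 0; den <- 0
  for (ci in seq_along(bm$control_points)) {
    cp <- bm$control_points[[ci]]
    act <- o_active(cp, bm$machine)
    hits <- c()
    for (i in seq_len(bm$machine$leaf_pair_count - 1)) {
      if (!(act[i] && act[i + 1])) next
      hits <- c(hits, cp$bank_A[i] > cp$bank_B[i + 1] ||
                  cp$bank_A[i + 1] > cp$bank_B[i])
    }
    if (!length(hits)) next
    num <- num + w[ci] * mean(hits)
    den <- den + w[ci]
  }
  if (den == 0) NA_real_ else num / den
}

o_kin <- function(bm) {
  ncp <- length(bm$control_points)
  machine <- bm$machine
  ever <- logical(machine$leaf_pair_count)
  for (ci in seq_len(ncp)) ever <- ever | o_active(bm$control_points[[ci]], machine)
  t <- sapply(bm$control_points, function(cp) cp$nominal_time)
  cum <- sapply(bm$control_points, function(cp) cp$cumulative_mu_fraction)
  ang <- sapply(bm$control_points, function(cp) cp$gantry_angle)
  dt <- diff(t)
  sp <- matrix(NA_real_, 2 * sum(ever), ncp - 1)
  row <- 0
  for (i in which(ever)) {
    row <- row + 1
    for (ci in 2:ncp)
      sp[row, ci - 1] <- abs(bm$control_points[[ci]]$bank_A[i] -
                               bm$control_points[[ci - 1]]$bank_A[i]) / dt[ci - 1]
  }
  for (i in which(ever)) {
    row <- row + 1
    for (ci in 2:ncp)
      sp[row, ci - 1] <- abs(bm$control_points[[ci]]$bank_B[i] -
                               bm$control_points[[ci - 1]]$bank_B[i]) / dt[ci - 1]
  }
  list(dt = dt, w = diff(cum), sp = sp,
       dr = diff(cum) * bm$total_mu / dt * 60, gs = abs(diff(ang)) / dt)
}

oracle_dynamics <- function(bm) {
  if (bm$technique == "static-IMRT" || length(bm$control_points) < 2) {
    return(NULL)  # convention path, not oracle-checked
  }
  k <- o_kin(bm)
  wmean <- function(x, w) sum(w * x) / sum(w)
  wsd <- function(x, w) sqrt(sum(w * (x - wmean(x, w))^2) / sum(w))
  wl <- c(); xl <- c()
  for (r in seq_len(nrow(k$sp))) {
    xl <- c(xl, k$sp[r, ])
    wl <- c(wl, k$w / nrow(k$sp))
  }
  list(mean_mlc_speed = wmean(xl, wl), mlc_speed_modulation = wsd(xl, wl),
       mean_dose_rate = wmean(k$dr, k$w), dose_rate_modulation = wsd(k$dr, k$w),
       mean_gantry_speed = wmean(k$gs, k$w),
       gantry_speed_modulation = wsd(k$gs, k$w))
}

oracle_mi_total <- function(bm, a_ref = 40, dr_ref = 300, gs_ref = 3) {
  if (length(bm$control_points) < 3) return(NA_real_)
  if (bm$technique == "static-IMRT") return(0)
  k <- o_kin(bm)
  nint <- length(k$dt)
  chs <- c(); wts <- c()
  for (r in seq_len(nrow(k$sp))) {
    for (j in seq_len(nint - 1)) {
      ch <- k$sp[r, j + 1] - k$sp[r, j]
      acc <- abs(ch) / ((k$dt[j] + k$dt[j + 1]) / 2)
      wt <- (1 + acc / a_ref) *
        (1 + abs(k$dr[j + 1] - k$dr[j]) / dr_ref) *
        (1 + abs(k$gs[j + 1] - k$gs[j]) / gs_ref)
      chs <- c(chs, ch); wts <- c(wts, wt)
    }
  }
  sigma <- sd(chs)
  if (!is.finite(sigma) || sigma <= 1e-9 * max(1, max(abs(k$sp)))) return(0)
  fs <- seq(0, 1, length.out = 100)
  z <- sapply(fs, function(f) sum(wts[abs(chs) > f * sigma]) / sum(wts))
  sum((z[-1] + z[-length(z)]) / 2 * diff(fs))
}

# regression oracle via stats::lm
oracle_ols <- function(x, y) {
  fit <- stats::lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}
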