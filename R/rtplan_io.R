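#' Write a plan to a DICOM RT Plan file
#'
#' Emits an explicit-VR little-endian part-10 RT Plan carrying the beam
#' sequence, per-beam MLC leaf boundaries, the control-point sequence (MLC
#' and jaw positions, gantry angle, cumulative meterset weight, dose rate)
#' and per-beam metersets in the fraction-group sequence. Leaf positions are
#' stored in bank order A (negative side) then B, matching `MLCX`
#' LeafJawPositions. Static beams with a single control point are expanded to
#' the conventional start/end pair of control points with weights 0 and 1.
#'
#' `nominal_time` is not a DICOM attribute; it is recoverable because the
#' stored `DoseRateSet` holds the mean dose rate of the interval ending at
#' each control point (see [read_rtplan()]).
#'
#' @param plan An [rt_plan()]; must pass [validate_plan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rtplan <- function(plan, path) {
  viol <- validate_plan(plan)
  if (length(viol)) {
    stop("invalid plan, refusing to write: ", paste(viol, collapse = "; "))
  }
  sop_uid <- dcm_new_uid()

  beam_items <- list()
  refbeam_items <- list()
  for (bi in seq_along(plan$beams)) {
    bm <- plan$beams[[bi]]
    cps <- bm$control_points
    if (length(cps) == 1L) {  # static convention: start/end pair
      cp0 <- cps[[1]]; cp0$cumulative_mu_fraction <- 0
      cp1 <- cps[[1]]; cp1$cumulative_mu_fraction <- 1
      cps <- list(cp0, cp1)
    }
    bld <- dcm_element(0x300A, 0x00B6, "SQ", list(
      c(dcm_str_element(0x300A, 0x00B8, "CS", "MLCX"),
        dcm_is(0x300A, 0x00BC, bm$machine$leaf_pair_count),
        dcm_ds(0x300A, 0x00BE, bm$machine$leaf_boundaries, digits = 2))
    ))
    cp_items <- lapply(seq_along(cps), function(ci) {
      cp <- cps[[ci]]
      pos_items <- list(
        c(dcm_str_element(0x300A, 0x00B8, "CS", "ASYMX"),
          dcm_ds(0x300A, 0x011C, c(cp$jaw_x1, cp$jaw_x2), digits = 4)),
        c(dcm_str_element(0x300A, 0x00B8, "CS", "ASYMY"),
          dcm_ds(0x300A, 0x011C, c(cp$jaw_y1, cp$jaw_y2), digits = 4)),
        c(dcm_str_element(0x300A, 0x00B8, "CS", "MLCX"),
          dcm_ds(0x300A, 0x011C, c(cp$bank_A, cp$bank_B)))
      )
      c(dcm_is(0x300A, 0x0112, ci - 1L),
        dcm_ds(0x300A, 0x0115, cp$dose_rate, digits = 4),
        dcm_ds(0x300A, 0x011E, cp$gantry_angle, digits = 4),
        dcm_element(0x300A, 0x011A, "SQ", pos_items),
        dcm_ds(0x300A, 0x0134, cp$cumulative_mu_fraction, digits = 9))
    })
    beam_items[[bi]] <- c(
      dcm_str_element(0x300A, 0x00C2, "LO", sprintf("B%d", bi)),
      dcm_str_element(0x300A, 0x00C3, "ST", bm$technique),
      dcm_str_element(0x300A, 0x00C4, "CS",
                      if (bm$technique == "static-IMRT") "STATIC" else "DYNAMIC"),
      bld,
      dcm_is(0x300A, 0x00C0, bi),
      dcm_ds(0x300A, 0x010E, 1.0, digits = 1),
      dcm_is(0x300A, 0x0110, length(cp_items)),
      dcm_element(0x300A, 0x0111, "SQ", cp_items)
    )
    refbeam_items[[bi]] <- c(
      dcm_ds(0x300A, 0x0086, bm$total_mu, digits = 6),
      dcm_is(0x300C, 0x0006, bi)
    )
  }

  body <- c(
    dcm_str_element(0x0008, 0x0016, "UI", .dcm_uid_rtplan),
    dcm_str_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_str_element(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_str_element(0x300A, 0x0002, "SH", substr(plan$plan_id, 1, 16)),
    dcm_str_element(0x300A, 0x0003, "LO", plan$plan_id),
    dcm_str_element(0x300A, 0x0004, "ST", plan$site_label),
    dcm_element(0x300A, 0x0070, "SQ", list(c(
      dcm_is(0x300A, 0x0071, 1L),
      dcm_element(0x300C, 0x0004, "SQ", refbeam_items)
    ))),
    dcm_element(0x300A, 0x00B0, "SQ", beam_items)
  )
  dcm_write_file(path, body, sop_uid)
  invisible(path)
}

#' Read a DICOM RT Plan file
#'
#' Parses the subset of RT Plan written by [write_rtplan()] (explicit VR
#' little endian): the beam sequence with 120-leaf `MLCX` geometry, control
#' points in delivery order, jaws carried forward when omitted, and per-beam
#' metersets. Cumulative meterset weights are normalized to `[0, 1]` per
#' beam. `nominal_time` is reconstructed from the cumulative MU and the
#' stored per-interval dose rate.
#'
#' @param path Path to an RT Plan file.
#' @return An [rt_plan()].
#' @export
read_rtplan <- function(path) {
  ds <- dcm_read_file(path)
  modality <- dcm_get_str(ds, "00080060")
  if (is.null(modality) || modality != "RTPLAN")
    stop("unsupported plan: not an RT Plan object")
  plan_id <- dcm_get_str(ds, "300a0003")
  if (is.null(plan_id)) plan_id <- dcm_get_str(ds, "300a0002")
  site <- dcm_get_str(ds, "300a0004")
  if (is.null(site) || !site %in% c("prostate", "lung", "head_and_neck",
                                    "brain", "mesothelioma")) site <- "other"

  # beam number -> meterset
  mu_map <- list()
  fg <- ds[["300a0070"]]
  if (!is.null(fg)) {
    for (item in fg$items) {
      rbs <- item[["300c0004"]]
      if (is.null(rbs)) next
      for (rb in rbs$items) {
        bn <- dcm_get_num(rb, "300c0006")
        mu_map[[as.character(bn)]] <- dcm_get_num(rb, "300a0086")
      }
    }
  }

  bseq <- ds[["300a00b0"]]
  if (is.null(bseq) || length(bseq$items) == 0)
    stop("malformed plan: no beam sequence")
  beams <- lapply(bseq$items, function(bitem) {
    technique <- dcm_get_str(bitem, "300a00c3")
    if (is.null(technique) ||
        !technique %in% c("static-IMRT", "sliding-window", "VMAT-arc")) {
      btype <- dcm_get_str(bitem, "300a00c4")
      technique <- if (identical(btype, "STATIC")) "static-IMRT" else "VMAT-arc"
    }
    geo <- machine_geometry()
    has_mlc <- FALSE
    bld <- bitem[["300a00b6"]]
    if (!is.null(bld)) {
      for (dev in bld$items) {
        if (identical(dcm_get_str(dev, "300a00b8"), "MLCX")) {
          has_mlc <- TRUE
          bounds <- dcm_get_num(dev, "300a00be")
          npairs <- dcm_get_num(dev, "300a00bc")
          if (!is.null(bounds) && length(bounds) >= 2) {
            if (length(bounds) - 1 != 60)
              stop("unsupported machine: expected 60 leaf pairs, got ",
                   length(bounds) - 1)
            geo <- machine_geometry(leaf_widths = diff(bounds))
          } else if (!is.null(npairs) && npairs != 60) {
            stop("unsupported machine: expected 60 leaf pairs, got ", npairs)
          }
        }
      }
    }
    cpseq <- bitem[["300a0111"]]
    if (is.null(cpseq) || length(cpseq$items) == 0)
      stop("unsupported plan: beam without control-point sequence")
    npair <- geo$leaf_pair_count

    jaw <- c(-200, 200, -200, 200)
    cps <- vector("list", length(cpseq$items))
    seen_mlc <- FALSE
    prev_A <- NULL; prev_B <- NULL
    cum <- numeric(length(cps))
    for (ci in seq_along(cpseq$items)) {
      item <- cpseq$items[[ci]]
      A <- prev_A; B <- prev_B
      pos <- item[["300a011a"]]
      if (!is.null(pos)) {
        for (dev in pos$items) {
          devtype <- dcm_get_str(dev, "300a00b8")
          vals <- dcm_get_num(dev, "300a011c")
          if (identical(devtype, "MLCX")) {
            if (length(vals) != 2 * npair)
              stop("unsupported machine: MLC position count ", length(vals),
                   " != ", 2 * npair)
            A <- vals[seq_len(npair)]
            B <- vals[npair + seq_len(npair)]
            seen_mlc <- TRUE
          } else if (identical(devtype, "ASYMX")) {
            jaw[1:2] <- vals
          } else if (identical(devtype, "ASYMY")) {
            jaw[3:4] <- vals
          }
        }
      }
      if (is.null(A)) A <- rep(0, npair)
      if (is.null(B)) B <- rep(0, npair)
      w <- dcm_get_num(item, "300a0134")
      cum[ci] <- if (is.null(w)) NA_real_ else w
      gantry <- dcm_get_num(item, "300a011e")
      dr <- dcm_get_num(item, "300a0115")
      cps[[ci]] <- control_point(
        cumulative_mu_fraction = cum[ci],
        gantry_angle = if (is.null(gantry)) 0 else gantry,
        bank_A = A, bank_B = B,
        jaw_x1 = jaw[1], jaw_x2 = jaw[2], jaw_y1 = jaw[3], jaw_y2 = jaw[4],
        dose_rate = if (is.null(dr)) 0 else dr
      )
      prev_A <- A; prev_B <- B
    }
    if (!seen_mlc)
      stop("unsupported plan: no MLC leaf-sequence data")
    if (any(diff(cum) < -1e-9))
      stop("malformed plan: non-monotonic cumulative meterset")
    final <- cum[length(cum)]
    if (!is.finite(final) || final <= 0)
      stop("malformed plan: final cumulative meterset not positive")
    cum <- cum / final
    total_mu <- mu_map[[as.character(
      dcm_get_num(bitem, "300a00c0"))]]
    if (is.null(total_mu)) total_mu <- 100

    # reconstruct nominal time from MU increments and interval dose rates
    tnom <- numeric(length(cps))
    for (ci in seq_along(cps)) {
      cps[[ci]]$cumulative_mu_fraction <- cum[ci]
      if (ci > 1) {
        dmu <- (cum[ci] - cum[ci - 1]) * total_mu
        dr <- cps[[ci]]$dose_rate
        dt <- if (dr > 0) dmu / dr * 60 else 0
        tnom[ci] <- tnom[ci - 1] + dt
      }
      cps[[ci]]$nominal_time <- tnom[ci]
    }

    angles <- vapply(cps, `[[`, numeric(1), "gantry_angle")
    arc_span <- if (technique == "VMAT-arc") abs(angles[length(angles)] - angles[1]) else 0
    beam(cps, total_mu = total_mu, technique = technique, machine = geo,
         arc_span = arc_span)
  })
  rt_plan(plan_id, site, beams)
}
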