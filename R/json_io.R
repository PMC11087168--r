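#' Serialize a plan to the package's JSON fixture dialect
#'
#' The dialect is stable and documented here by its field names:
#' `plan_id`, `site_label`, `beams[]` with `total_mu`, `technique`,
#' `arc_span`, `machine` (`leaf_widths`, `max_leaf_position`,
#' `min_dynamic_gap`) and `control_points[]` carrying every
#' [control_point()] field verbatim. Numbers are written with full precision
#' so that identical plans produce byte-identical JSON.
#'
#' @param plan An [rt_plan()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly, when `path` is given).
#' @export
plan_to_json <- function(plan, path = NULL) {
  beams <- lapply(plan$beams, function(bm) {
    list(
      total_mu = bm$total_mu,
      technique = bm$technique,
      arc_span = bm$arc_span,
      machine = list(
        leaf_widths = bm$machine$leaf_widths,
        max_leaf_position = bm$machine$max_leaf_position,
        min_dynamic_gap = bm$machine$min_dynamic_gap
      ),
      control_points = lapply(bm$control_points, function(cp) {
        unclass(cp)
      })
    )
  })
  obj <- list(plan_id = plan$plan_id, site_label = plan$site_label, beams = beams)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a plan from the JSON fixture dialect
#'
#' @param x A file path or a JSON string produced by [plan_to_json()].
#' @return An [rt_plan()].
#' @export
plan_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  beams <- lapply(obj$beams, function(b) {
    geo <- machine_geometry(leaf_widths = b$machine$leaf_widths,
                            max_leaf_position = b$machine$max_leaf_position,
                            min_dynamic_gap = b$machine$min_dynamic_gap)
    cps <- lapply(b$control_points, function(cp) {
      do.call(control_point, c(
        list(cumulative_mu_fraction = cp$cumulative_mu_fraction,
             gantry_angle = cp$gantry_angle,
             bank_A = cp$bank_A, bank_B = cp$bank_B,
             jaw_x1 = cp$jaw_x1, jaw_x2 = cp$jaw_x2,
             jaw_y1 = cp$jaw_y1, jaw_y2 = cp$jaw_y2,
             nominal_time = cp$nominal_time, dose_rate = cp$dose_rate)))
    })
    beam(cps, total_mu = b$total_mu, technique = b$technique,
         machine = geo, arc_span = b$arc_span)
  })
  rt_plan(obj$plan_id, obj$site_label, beams)
}
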