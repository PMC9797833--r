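#' Select end-diastole and end-systole from a cine segmentation
#'
#' End-diastole is the phase with the largest 3D LV blood-pool volume,
#' end-systole the phase with the smallest; ties are broken toward the
#' earliest phase. The selection is global (one ED/ES pair per study, used
#' by every view), so strain, fractional area change and ejection fraction
#' are all referenced to the same pair of timeframes.
#'
#' @param cine a [cine_segmentation()].
#' @param per_view_areas optional numeric vector of per-phase slice areas;
#'   when supplied, ED/ES are chosen from these instead of the 3D volumes
#'   (per-view mode).
#' @return list with `ed` and `es` (1-based phase indices) and `volumes`.
#' @export
select_ed_es <- function(cine, per_view_areas = NULL) {
  v <- if (is.null(per_view_areas)) lv_volumes(cine) else per_view_areas
  stopifnot(length(v) >= 2L)
  ed <- which.max(v)
  es <- which.min(v)
  if (ed == es) {
    warning("constant LV volume across phases: strain will be zero")
    ed <- 1L
    es <- if (ed == 1L) 2L else 1L
  }
  list(ed = as.integer(ed), es = as.integer(es), volumes = v)
}

#' Per-view perimeter and area time curves
#'
#' @param view view tag.
#' @param perimeters named list (per method) of per-phase perimeter lengths
#'   (mm).
#' @param areas per-phase LV cavity areas of the slice (mm^2).
#' @param ed,es 1-based ED and ES phase indices.
#' @param compliant logical: `FALSE` when the mitral interface was missing.
#' @return object of class `view_curve`.
#' @export
view_curve <- function(view, perimeters, areas, ed, es, compliant = TRUE) {
  stopifnot(is.list(perimeters), length(perimeters) >= 1L)
  np <- length(areas)
  for (p in perimeters) stopifnot(length(p) == np)
  stopifnot(ed != es, ed >= 1L, es >= 1L, ed <= np, es <= np)
  structure(list(view = view, perimeters = perimeters, areas = areas,
                 ed = as.integer(ed), es = as.integer(es), compliant = compliant),
            class = "view_curve")
}

#' Longitudinal strain of one view
#'
#' `LS = (P_ES - P_ED) / P_ED`, dimensionless; negative values indicate
#' longitudinal shortening. All method curves share the study's ED/ES pair.
#'
#' @param curve a [view_curve()].
#' @param method which perimeter method's curve to use.
#' @return signed strain fraction (multiply by 100 for percent).
#' @export
longitudinal_strain <- function(curve, method = "spline") {
  stopifnot(inherits(curve, "view_curve"))
  p <- curve$perimeters[[method]]
  if (is.null(p)) stop("no perimeter curve for method: ", method)
  p_ed <- p[curve$ed]
  if (!is.finite(p_ed) || p_ed <= 0) stop("end-diastolic perimeter missing or non-positive")
  (p[curve$es] - p_ed) / p_ed
}

#' Fractional area change of one view
#'
#' `FAC = (A_ED - A_ES) / A_ED` from raw LV pixel areas of the view slice.
#'
#' @param curve a [view_curve()].
#' @return FAC fraction.
#' @export
fractional_area_change <- function(curve) {
  stopifnot(inherits(curve, "view_curve"))
  a_ed <- curve$areas[curve$ed]
  if (!is.finite(a_ed) || a_ed <= 0) stop("end-diastolic area missing or non-positive")
  (a_ed - curve$areas[curve$es]) / a_ed
}

#' Ejection fraction from 3D LV volumes
#'
#' `EF = (EDV - ESV) / EDV` with volumes taken at the study's ED/ES phases.
#'
#' @param cine a [cine_segmentation()].
#' @param ed,es optional phase indices; selected via [select_ed_es()] when
#'   omitted.
#' @return EF fraction.
#' @export
ejection_fraction <- function(cine, ed = NULL, es = NULL) {
  v <- lv_volumes(cine)
  if (is.null(ed) || is.null(es)) {
    sel <- select_ed_es(cine)
    ed <- sel$ed; es <- sel$es
  }
  if (v[ed] <= 0) stop("end-diastolic volume is zero")
  (v[ed] - v[es]) / v[ed]
}
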