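#' Pipeline configuration
#'
#' Collects every tunable of the strain pipeline in one explicit, serialisable
#' object so a run is fully reproducible from its config.
#'
#' @param pixel_spacing reslicing pixel spacing (mm); `NULL` = smallest voxel
#'   dimension.
#' @param extent reslicing extent (mm half-widths) or `NULL` for automatic.
#' @param disk_radius disk structuring-element radius in pixels for the
#'   morphological closing.
#' @param downsample downsampling factor of the hull curve before spline
#'   fitting.
#' @param methods perimeter methods to compute.
#' @param classify_method method whose LS is used for classification.
#' @param all_phases compute perimeter/area curves for every phase (`TRUE`)
#'   or only at ED/ES (`FALSE`; other entries are `NA`).
#' @param per_view_ed_es select ED/ES per view from slice areas instead of
#'   globally from 3D volumes.
#' @return object of class `strain_config`.
#' @export
strain_config <- function(pixel_spacing = NULL, extent = NULL,
                          disk_radius = 10L, downsample = 5L,
                          methods = c("naive", "hull", "spline"),
                          classify_method = "spline",
                          all_phases = TRUE, per_view_ed_es = FALSE) {
  methods <- match.arg(methods, c("naive", "hull", "spline"), several.ok = TRUE)
  stopifnot(classify_method %in% methods, disk_radius >= 0, downsample >= 1)
  structure(list(pixel_spacing = pixel_spacing, extent = extent,
                 disk_radius = as.integer(disk_radius),
                 downsample = as.integer(downsample),
                 methods = methods, classify_method = classify_method,
                 all_phases = all_phases, per_view_ed_es = per_view_ed_es),
            class = "strain_config")
}

#' Run the strain pipeline on one study
#'
#' Reslices every long-axis plane across the cardiac cycle, measures the
#' endocardial perimeter with the configured methods, and assembles LS, FAC
#' and EF. A view whose slice lacks the LA (no mitral interface) or fails to
#' produce a contour is downgraded to non-compliant rather than aborting the
#' study.
#'
#' @param cine a [cine_segmentation()].
#' @param planes list of [plane_definition()]s.
#' @param config a [strain_config()].
#' @param study_id identifier recorded in the results table.
#' @return object of class `study_result`: `table` (one row per view x
#'   method with P_ED, P_ES, LS, FAC, ED/ES phases, EF and compliance),
#'   `curves` (per-view [view_curve()]s), `ef`, `ed`, `es`.
#' @export
run_study <- function(cine, planes, config = strain_config(), study_id = "study") {
  stopifnot(inherits(cine, "cine_segmentation"))
  sel <- select_ed_es(cine)
  ef <- ejection_fraction(cine, sel$ed, sel$es)
  np <- length(cine$frames)
  curves <- list()
  rows <- list()
  for (pl in planes) {
    phases <- if (config$all_phases) seq_len(np) else sort(unique(c(sel$ed, sel$es)))
    perims <- lapply(config$methods, function(m) rep(NA_real_, np))
    names(perims) <- config$methods
    areas <- rep(NA_real_, np)
    compliant <- TRUE
    failed <- FALSE
    for (ph in phases) {
      ok <- tryCatch({
        sl <- suppressWarnings(reslice(cine, pl, phase = ph,
                                       pixel_spacing = config$pixel_spacing,
                                       extent = config$extent))
        areas[ph] <- slice_lv_area(sl)
        if (sl$empty || !any(sl$labels == 1L)) {
          FALSE
        } else {
          ms <- suppressWarnings(measure_perimeters(
            sl, methods = config$methods,
            disk_radius = config$disk_radius, downsample = config$downsample))
          for (m in names(ms)) {
            perims[[m]][ph] <- ms[[m]]$length_mm
            if (!ms[[m]]$compliant) compliant <- FALSE
          }
          TRUE
        }
      }, error = function(e) FALSE)
      if (!ok) { failed <- TRUE; compliant <- FALSE }
    }
    if (config$per_view_ed_es && !all(is.na(areas))) {
      vsel <- select_ed_es(cine, per_view_areas = areas)
      ed <- vsel$ed; es <- vsel$es
    } else { ed <- sel$ed; es <- sel$es }
    cv <- view_curve(pl$view, perims, areas, ed, es, compliant = compliant && !failed)
    curves[[pl$view]] <- cv
    for (m in config$methods) {
      ls <- tryCatch(longitudinal_strain(cv, m), error = function(e) NA_real_)
      fac <- tryCatch(fractional_area_change(cv), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        study = study_id, view = pl$view, method = m,
        p_ed = perims[[m]][ed], p_es = perims[[m]][es],
        ls = ls, fac = fac, ed_phase = ed, es_phase = es, ef = ef,
        compliant = compliant && !failed, stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows), curves = curves,
                 ef = ef, ed = sel$ed, es = sel$es, study_id = study_id),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result '%s': EF %.3f (ED phase %d, ES phase %d)\n",
              x$study_id, x$ef, x$ed, x$es))
  print(x$table[, c("view", "method", "p_ed", "p_es", "ls", "fac", "compliant")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit LS cutoffs on a training table
#'
#' Fits per-view optimal cutoffs and the single pooled cutoff by
#' [roc_and_optimal_cutoff()] on per-view LS values against the binary
#' wall-motion truth.
#'
#' @param ls_table data.frame with columns `study`, `view`, `ls`, `abnormal`.
#' @return list with `per_view` (named numeric), `single` (numeric), and the
#'   underlying `roc` objects. A view whose training data contain only one
#'   class cannot support its own ROC curve; it inherits the pooled cutoff
#'   (recorded in `fallback_views`).
#' @export
fit_thresholds <- function(ls_table) {
  stopifnot(all(c("study", "view", "ls", "abnormal") %in% names(ls_table)))
  if (all(ls_table$abnormal) || !any(ls_table$abnormal))
    stop("training cohort contains a single class: cannot fit cutoffs")
  pooled <- roc_and_optimal_cutoff(ls_table$ls, ls_table$abnormal)
  views <- sort(unique(ls_table$view))
  rocs <- lapply(views, function(v) {
    d <- ls_table[ls_table$view == v, ]
    if (all(d$abnormal) || !any(d$abnormal)) return(NULL)
    roc_and_optimal_cutoff(d$ls, d$abnormal)
  })
  names(rocs) <- views
  fallback <- views[vapply(rocs, is.null, logical(1))]
  per_view <- vapply(views, function(v)
    if (is.null(rocs[[v]])) pooled$tau else rocs[[v]]$tau, numeric(1))
  list(per_view = per_view, single = pooled$tau,
       roc = c(rocs[!vapply(rocs, is.null, logical(1))], list(pooled = pooled)),
       fallback_views = fallback)
}

#' Evaluate fitted cutoffs on a cohort table
#'
#' Applies per-view and single-threshold classification to a cohort's LS
#' table and reports view-level (per view and pooled) and patient-level
#' confusion metrics, mirroring the training/testing evaluation design.
#'
#' @param ls_table data.frame with `study`, `view`, `ls`, `abnormal` (view
#'   truth) and `study_abnormal` (patient truth).
#' @param thresholds result of [fit_thresholds()] (or a compatible list).
#' @return nested list: `$individual` and `$single`, each with `views`
#'   (per-view [confusion_metrics()]), `pooled_views`, and `patient`.
#' @export
evaluate_thresholds <- function(ls_table, thresholds) {
  stopifnot(all(c("study", "view", "ls", "abnormal", "study_abnormal") %in% names(ls_table)))
  eval_mode <- function(tau) {
    pred <- if (length(tau) == 1L && is.null(names(tau)))
      classify_view(ls_table$ls, thresholds = tau)
    else classify_view(ls_table$ls, ls_table$view, tau)
    per_view <- lapply(sort(unique(ls_table$view)), function(v) {
      i <- ls_table$view == v
      confusion_metrics(pred[i], ls_table$abnormal[i])
    })
    names(per_view) <- sort(unique(ls_table$view))
    d <- data.frame(study = ls_table$study, pred = pred,
                    truth = ls_table$study_abnormal)
    pat <- stats::aggregate(cbind(pred, truth) ~ study, d,
                            FUN = function(x) any(as.logical(x)))
    list(views = per_view,
         pooled_views = confusion_metrics(pred, ls_table$abnormal),
         patient = confusion_metrics(pat$pred, pat$truth),
         predictions = data.frame(ls_table[c("study", "view")], pred = pred))
  }
  list(individual = eval_mode(thresholds$per_view),
       single = eval_mode(unname(thresholds$single)))
}

#' Run a training/testing cohort analysis
#'
#' Orchestrates the full design: the strain pipeline is run on every
#' analyzable study, LS cutoffs are fitted on the training records only, and
#' both per-view and single-threshold classification performance is reported
#' separately for each cohort. Studies whose pipeline fails are flagged and
#' excluded with their failure reason, never silently dropped.
#'
#' @param records list of study records, each a list with `id`, `cine`,
#'   `planes`, `role` (`"train"` or `"test"`), and truth: either
#'   `truth_views` (named logical per view) or `expert_labels` (data.frame
#'   for [consensus_view_labels()]).
#' @param config a [strain_config()].
#' @param thresholds optional pre-fitted thresholds (testing-only run).
#' @return object of class `cohort_report`: `thresholds`, `train`/`test`
#'   evaluation lists, `ls_table`, `failures`.
#' @export
run_cohort <- function(records, config = strain_config(), thresholds = NULL) {
  stopifnot(length(records) >= 1L)
  rows <- list(); failures <- list()
  for (rec in records) {
    res <- tryCatch(run_study(rec$cine, rec$planes, config, study_id = rec$id),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[rec$id]] <- conditionMessage(res)
      next
    }
    tab <- res$table[res$table$method == config$classify_method, ]
    tv <- if (!is.null(rec$truth_views)) rec$truth_views
    else {
      cons <- consensus_view_labels(rec$expert_labels)
      stats::setNames(cons$views$abnormal, cons$views$view)
    }
    tab$abnormal <- as.logical(tv[tab$view])
    tab$study_abnormal <- any(tab$abnormal)
    tab$role <- rec$role
    rows[[length(rows) + 1L]] <- tab
  }
  if (length(rows) == 0L)
    stop("every study in the cohort failed: ",
         paste(names(failures), unlist(failures), sep = ": ", collapse = "; "))
  ls_table <- do.call(rbind, rows)
  ls_table <- ls_table[is.finite(ls_table$ls), ]
  train <- ls_table[ls_table$role == "train", ]
  test <- ls_table[ls_table$role == "test", ]
  if (is.null(thresholds)) {
    if (nrow(train) == 0L) stop("no analyzable training studies to fit thresholds on")
    thresholds <- fit_thresholds(train)
  }
  structure(list(
    thresholds = thresholds,
    train = if (nrow(train) > 0L) evaluate_thresholds(train, thresholds) else NULL,
    test = if (nrow(test) > 0L) evaluate_thresholds(test, thresholds) else NULL,
    ls_table = ls_table, failures = failures
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort_report\n  per-view cutoffs:",
      paste(sprintf("%s %.4f", names(x$thresholds$per_view), x$thresholds$per_view),
            collapse = ", "),
      sprintf("\n  single cutoff: %.4f\n", x$thresholds$single))
  if (!is.null(x$test)) {
    cat("  testing, per-patient (individual thresholds):\n")
    print(x$test$individual$patient)
  }
  if (length(x$failures))
    cat("  failed studies:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
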