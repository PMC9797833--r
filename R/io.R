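#' Write a cine segmentation as NIfTI
#'
#' @param cine a [cine_segmentation()].
#' @param path output path. With `split = FALSE` a single 4D file is
#'   written; with `split = TRUE`, `path` is treated as a stem and one 3D
#'   file per phase (`<stem>_phNN.nii.gz`) is written.
#' @param split write one file per phase.
#' @return invisibly, the file path(s) written.
#' @export
write_cine_nifti <- function(cine, path, split = FALSE) {
  stopifnot(inherits(cine, "cine_segmentation"))
  aff <- structure(cine$affine, code = 2L)
  if (!split) {
    arr <- array(0L, c(cine$dim, length(cine$frames)))
    for (k in seq_along(cine$frames)) arr[, , , k] <- cine$frames[[k]]
    img <- RNifti::asNifti(arr)
    RNifti::sform(img) <- aff
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  paths <- sprintf("%s_ph%02d.nii.gz", stem, seq_along(cine$frames))
  for (k in seq_along(cine$frames)) {
    img <- RNifti::asNifti(cine$frames[[k]])
    RNifti::sform(img) <- aff
    RNifti::writeNifti(img, paths[k])
  }
  invisible(paths)
}

#' Read a cine segmentation from NIfTI
#'
#' Accepts either one 4D file or a vector of per-phase 3D files (ordered).
#' The file's sform/qform affine is honoured as the voxel-to-world transform.
#'
#' @param paths one 4D NIfTI path or a character vector of 3D paths.
#' @param phase_pct optional per-frame phase percentages.
#' @return a [cine_segmentation()].
#' @export
read_cine_nifti <- function(paths, phase_pct = NULL) {
  imgs <- lapply(paths, RNifti::readNifti)
  aff <- matrix(as.numeric(unclass(RNifti::xform(imgs[[1]]))), 4, 4)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (length(imgs) == 1L && length(dim(imgs[[1]])) == 4L) {
    arr <- imgs[[1]]
    frames <- lapply(seq_len(dim(arr)[4]), function(k) {
      f <- array(as.integer(round(arr[, , , k])), dim(arr)[1:3])
      f
    })
  } else {
    frames <- lapply(imgs, function(im) array(as.integer(round(im)), dim(im)[1:3]))
  }
  cine_segmentation(frames, spacing = spacing, affine = aff,
                    phase_pct = phase_pct)
}

#' Write and read long-axis plane definitions as JSON
#'
#' Planes are stored as a JSON array of objects
#' `{"view": "2CH", "origin_mm": [...], "x_dir": [...], "y_dir": [...]}`.
#'
#' @param planes list of [plane_definition()]s.
#' @param path JSON file path.
#' @return `write_planes_json` returns the path invisibly;
#'   `read_planes_json` returns a named list of [plane_definition()]s.
#' @export
write_planes_json <- function(planes, path) {
  obj <- lapply(planes, function(p)
    list(view = p$view, origin_mm = p$origin, x_dir = p$x_dir, y_dir = p$y_dir))
  jsonlite::write_json(unname(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_planes_json
#' @export
read_planes_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(obj)) obj <- split(obj, seq_len(nrow(obj)))
  planes <- lapply(obj, function(p) {
    for (f in c("view", "origin_mm", "x_dir", "y_dir"))
      if (is.null(p[[f]]) || (is.data.frame(p) && !f %in% names(p)))
        stop("malformed plane definition: missing field '", f, "'")
    plane_definition(as.character(p$view[[1]]),
                     origin = unlist(p$origin_mm), x_dir = unlist(p$x_dir),
                     y_dir = unlist(p$y_dir))
  })
  names(planes) <- vapply(planes, function(p) p$view, character(1))
  planes
}

#' Write and read fitted LS thresholds as JSON
#'
#' @param thresholds list with `per_view` (named numeric) and `single`.
#' @param path JSON file path.
#' @return `write_thresholds_json` returns the path invisibly;
#'   `read_thresholds_json` returns the thresholds list.
#' @export
write_thresholds_json <- function(thresholds, path) {
  jsonlite::write_json(list(per_view = as.list(thresholds$per_view),
                            single = unname(thresholds$single)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(per_view = unlist(obj$per_view), single = obj$single)
}

#' Read expert wall-motion labels from CSV
#'
#' Expected columns: `study`, `reader`, `segment` (1-16), `label`.
#'
#' @param path CSV path.
#' @return data.frame suitable for [consensus_view_labels()].
#' @export
read_expert_labels <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("study", "reader", "segment", "label")
  if (!all(req %in% names(d)))
    stop("expert label CSV must have columns: ", paste(req, collapse = ", "))
  d$segment <- as.integer(d$segment)
  d
}

#' Write a study or cohort results table as CSV
#'
#' @param x a `study_result`, `cohort_report`, or plain data.frame.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_results_csv <- function(x, path) {
  tab <- if (inherits(x, "study_result")) x$table
  else if (inherits(x, "cohort_report")) x$ls_table
  else as.data.frame(x)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a generated phantom to disk
#'
#' Phases as NIfTI (4D by default), plane definitions as JSON, and the
#' analytic truth as CSV.
#'
#' @param phantom a `ct_phantom` from [generate_phantom()].
#' @param dir output directory (created if needed).
#' @param split_phases write one NIfTI per phase instead of a 4D file.
#' @return invisibly, the directory.
#' @export
write_phantom <- function(phantom, dir, split_phases = FALSE) {
  stopifnot(inherits(phantom, "ct_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cine_nifti(phantom$cine, file.path(dir, "labels.nii.gz"), split = split_phases)
  write_planes_json(phantom$planes, file.path(dir, "planes.json"))
  tr <- phantom$truth
  truth_df <- data.frame(
    view = rownames(tr$perimeter),
    ls_true = tr$ls, fac_true = tr$fac, ef_true = tr$ef,
    ed_phase = tr$ed_phase, es_phase = tr$es_phase,
    abnormal = tr$abnormal_views, row.names = NULL)
  utils::write.csv(truth_df, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(view = rownames(tr$perimeter), tr$perimeter, row.names = NULL),
    file.path(dir, "truth_perimeters.csv"), row.names = FALSE)
  invisible(dir)
}
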