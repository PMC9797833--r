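#' Time-resolved label segmentation of the left heart
#'
#' Container for an ordered set of 3D integer label volumes (0 = background,
#' 1 = LV blood pool, 2 = LA blood pool) sharing one voxel grid and world
#' transform. World coordinates are in mm; voxel indices are 0-based in the
#' transform convention, and a world point belongs to the voxel whose centre
#' is nearest (nearest-neighbour convention used throughout).
#'
#' @param frames list of 3D integer arrays with identical dimensions.
#' @param spacing voxel spacing per axis (mm); scalar recycled to 3.
#' @param origin world coordinates (mm) of the centre of voxel (0,0,0).
#'   Ignored when `affine` is given.
#' @param affine optional 4x4 matrix mapping homogeneous 0-based voxel
#'   indices to world mm (NIfTI-style); defaults to `diag(spacing)` with
#'   translation `origin`.
#' @param phase_pct optional per-frame phase as percent of the R-R interval.
#' @return Object of class `cine_segmentation`.
#' @export
cine_segmentation <- function(frames, spacing, origin = c(0, 0, 0),
                              affine = NULL, phase_pct = NULL) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  d <- dim(frames[[1]])
  stopifnot(length(d) == 3L)
  for (f in frames) {
    stopifnot(identical(dim(f), d))
    if (!all(f %in% c(0L, 1L, 2L))) stop("labels must be in {0, 1, 2}")
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(spacing)
    affine[1:3, 4] <- origin
  }
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (is.null(phase_pct)) phase_pct <- (seq_along(frames) - 1) * 100 / length(frames)
  structure(list(frames = frames, dim = d, spacing = spacing,
                 affine = affine, phase_pct = phase_pct),
            class = "cine_segmentation")
}

#' @export
print.cine_segmentation <- function(x, ...) {
  cat("cine_segmentation:", length(x$frames), "phases,",
      paste(x$dim, collapse = "x"), "voxels @",
      paste(signif(x$spacing, 4), collapse = "x"), "mm\n")
  invisible(x)
}

#' LV blood-pool volume per phase
#'
#' @param cine a [cine_segmentation()].
#' @return numeric vector of LV volumes in mm^3 (voxel count times voxel
#'   volume).
#' @export
lv_volumes <- function(cine) {
  stopifnot(inherits(cine, "cine_segmentation"))
  vv <- prod(cine$spacing)
  vapply(cine$frames, function(f) sum(f == 1L) * vv, numeric(1))
}

#' Long-axis imaging plane
#'
#' A plane in world coordinates given by its origin (the translation vector)
#' and two orthonormal in-plane direction vectors, tagged with the view it
#' represents.
#'
#' @param view one of `"2CH"`, `"3CH"`, `"4CH"`.
#' @param origin world point on the plane (mm).
#' @param x_dir,y_dir in-plane unit direction vectors; must be unit-norm and
#'   mutually orthogonal within 1e-6.
#' @return Object of class `plane_definition`.
#' @export
plane_definition <- function(view, origin, x_dir, y_dir) {
  view <- match.arg(view, c("2CH", "3CH", "4CH"))
  origin <- as.numeric(origin); x_dir <- as.numeric(x_dir); y_dir <- as.numeric(y_dir)
  stopifnot(length(origin) == 3L, length(x_dir) == 3L, length(y_dir) == 3L)
  if (abs(sqrt(sum(x_dir^2)) - 1) > 1e-6 || abs(sqrt(sum(y_dir^2)) - 1) > 1e-6)
    stop("plane direction vectors must be unit-norm")
  if (abs(sum(x_dir * y_dir)) > 1e-6)
    stop("plane direction vectors must be orthogonal")
  structure(list(view = view, origin = origin, x_dir = x_dir, y_dir = y_dir),
            class = "plane_definition")
}

#' 2D long-axis label slice
#'
#' @param labels integer matrix with values in {0, 1, 2}.
#' @param spacing isotropic pixel spacing (mm).
#' @param view,phase provenance tags.
#' @param empty logical, `TRUE` when the reslicing plane missed the volume.
#' @return Object of class `lax_slice`.
#' @export
lax_slice <- function(labels, spacing, view = NA_character_, phase = NA_integer_,
                      empty = FALSE) {
  labels <- matrix(as.integer(labels), nrow = nrow(labels))
  if (!all(labels %in% c(0L, 1L, 2L))) stop("labels must be in {0, 1, 2}")
  stopifnot(spacing > 0)
  structure(list(labels = labels, spacing = spacing, view = view,
                 phase = phase, empty = empty),
            class = "lax_slice")
}

#' Reslice a label volume along a long-axis plane
#'
#' Samples the volume on a regular 2D pixel grid spanned by the plane's
#' direction vectors. Labels are sampled nearest-neighbour (a pixel carries
#' the label of the voxel whose centre is nearest its world-space centre);
#' no label interpolation ever occurs. Pixels outside the volume are
#' background.
#'
#' @param cine a [cine_segmentation()], or a single 3D label array (then
#'   `affine` must be given).
#' @param plane a [plane_definition()].
#' @param phase phase index (1-based) when `cine` is a cine object.
#' @param pixel_spacing in-plane pixel spacing (mm); default: the smallest
#'   voxel dimension, so no boundary resolution is lost.
#' @param extent in-plane half-extents: `c(u, v)` in mm around the plane
#'   origin, or `NULL` to cover the bounding box of all non-background
#'   voxels plus a 6 mm margin.
#' @param affine 4x4 voxel-to-world matrix when `cine` is a bare array.
#' @return A [lax_slice()]; `empty` is set (with a warning) when the plane
#'   misses the labelled volume entirely.
#' @export
reslice <- function(cine, plane, phase = 1L, pixel_spacing = NULL,
                    extent = NULL, affine = NULL) {
  stopifnot(inherits(plane, "plane_definition"))
  if (inherits(cine, "cine_segmentation")) {
    vol <- cine$frames[[phase]]
    affine <- cine$affine
    spacing <- cine$spacing
  } else {
    vol <- cine
    if (is.null(affine)) stop("affine required when reslicing a bare array")
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  if (is.null(pixel_spacing)) pixel_spacing <- min(spacing)
  d <- dim(vol)

  if (is.null(extent)) {
    idx <- which(vol != 0L, arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      rng <- rbind(c(-1, 1), c(-1, 1)) * max(d * spacing) / 2
    } else {
      bb <- rbind(apply(idx, 2, min) - 1, apply(idx, 2, max) - 1)  # 0-based
      corners <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
      wc <- t(affine %*% t(cbind(corners, 1)))[, 1:3, drop = FALSE]
      rel <- sweep(wc, 2, plane$origin)
      rng <- rbind(range(rel %*% plane$x_dir), range(rel %*% plane$y_dir))
      rng <- rng + 6 * c(-1, 1, -1, 1)  # margin, mm
    }
    us <- seq(rng[1, 1], rng[1, 2], by = pixel_spacing)
    vs <- seq(rng[2, 1], rng[2, 2], by = pixel_spacing)
  } else {
    if (length(extent) == 1L) extent <- rep(extent, 2)
    us <- seq(-extent[1], extent[1], by = pixel_spacing)
    vs <- seq(-extent[2], extent[2], by = pixel_spacing)
  }

  nu <- length(us); nv <- length(vs)
  # world points of all slice pixels
  U <- rep(us, times = nv); V <- rep(vs, each = nu)
  W <- cbind(plane$origin[1] + U * plane$x_dir[1] + V * plane$y_dir[1],
             plane$origin[2] + U * plane$x_dir[2] + V * plane$y_dir[2],
             plane$origin[3] + U * plane$x_dir[3] + V * plane$y_dir[3], 1)
  ijk <- t(solve(affine) %*% t(W))[, 1:3, drop = FALSE]
  ijk <- round(ijk) + 1  # to 1-based indices
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  lab <- integer(nu * nv)
  if (any(ok)) lab[ok] <- vol[cbind(ijk[ok, 1], ijk[ok, 2], ijk[ok, 3])]
  empty <- !any(lab != 0L)
  if (empty) warning("reslicing plane misses the labelled volume: all-background slice")
  lax_slice(matrix(lab, nu, nv), spacing = pixel_spacing,
            view = plane$view, phase = phase, empty = empty)
}
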