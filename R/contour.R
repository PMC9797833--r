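#' @import EBImage
NULL

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so labels
# touching only diagonally are merged afterwards with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow = nrow(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  merge_pairs <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) return(invisible())
    for (p in unique(cbind(a[sel], b[sel])[, 1] * (n + 1L) + cbind(a[sel], b[sel])[, 2])) {
      i <- find(p %/% (n + 1L)); j <- find(p %% (n + 1L))
      if (i != j) parent[max(i, j)] <<- min(i, j)
    }
  }
  merge_pairs(lab[-nr, -nc], lab[-1, -1])   # \ diagonal
  merge_pairs(lab[-1, -nc], lab[-nr, -1])   # / diagonal
  root <- vapply(seq_len(n), find, integer(1))
  out <- lab
  out[lab > 0L] <- root[lab[lab > 0L]]
  out
}

largest_component_mask <- function(mask) {
  lab <- label_components8(mask)
  ids <- lab[lab > 0L]
  if (length(ids) == 0L) stop("no foreground pixels")
  tab <- tabulate(ids)
  keep <- which.max(tab)  # earliest label on ties
  structure(lab == keep, n_components = sum(tab > 0L))
}

# pixels of `mask` having at least one 4-neighbour outside the mask (image
# borders count as outside)
boundary4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
        pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  core & !nb
}

# Moore-neighbour contour tracing with Jacob's stopping criterion.
# Returns an ordered closed chain of boundary pixels as an n x 2 (row, col)
# matrix, traced with 8-connectivity, consistently oriented.
moore_trace <- function(mask) {
  npx <- sum(mask)
  if (npx == 0L) stop("no foreground pixels")
  idx <- which(mask)
  nr <- nrow(mask)
  if (npx == 1L) return(matrix(c((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L), 1, 2))
  # first pixel in column-major order: lexicographically smallest (col, row);
  # its column-wise predecessor is guaranteed background
  start <- c((idx[1] - 1L) %% nr + 1L, (idx[1] - 1L) %/% nr + 1L)
  # neighbour offsets in consistent circular order
  off <- matrix(c(0, -1,  -1, -1,  -1, 0,  -1, 1,  0, 1,  1, 1,  1, 0,  1, -1),
                ncol = 2, byrow = TRUE)
  inmask <- function(p) p[1] >= 1 && p[1] <= nrow(mask) && p[2] >= 1 &&
    p[2] <= ncol(mask) && mask[p[1], p[2]]
  # advance one Moore step: scan neighbours of cur circularly starting just
  # after the backtrack; return the next boundary pixel and its backtrack
  advance <- function(cur, bdir) {
    for (step in 1:8) {
      di <- (bdir + step - 1L) %% 8L + 1L
      cand <- cur + off[di, ]
      if (inmask(cand)) {
        prev <- (bdir + step - 2L) %% 8L + 1L  # last background scanned
        bp <- cur + off[prev, ]
        rel <- bp - cand
        return(list(p = cand, b = which(off[, 1] == rel[1] & off[, 2] == rel[2])))
      }
    }
    NULL
  }
  chain <- matrix(NA_integer_, 4L * npx + 8L, 2)
  chain[1, ] <- start
  nchain <- 1L
  cur <- start
  bdir <- 1L  # backtrack of the start pixel: its W neighbour (background)
  first <- NULL
  repeat {
    st <- advance(cur, bdir)
    if (is.null(st)) break  # isolated pixel (cannot happen for npx > 1 here)
    if (is.null(first)) {
      first <- st
    } else if (all(cur == start) && all(st$p == first$p) && st$b == first$b) {
      # about to repeat the initial move: the cycle is closed
      if (all(chain[nchain, ] == chain[1, ])) nchain <- nchain - 1L
      break
    }
    nchain <- nchain + 1L
    if (nchain > nrow(chain)) chain <- rbind(chain, chain)
    chain[nchain, ] <- st$p
    cur <- st$p
    bdir <- st$b
    if (nchain > 4L * npx + 4L) stop("contour tracing failed to terminate")
  }
  chain[seq_len(nchain), , drop = FALSE]
}

#' Extract the ordered LV boundary chain of a label slice
#'
#' Traces the closed boundary of the largest 8-connected LV component.
#' Boundary pixels are LV pixels with at least one 4-neighbour that is not
#' LV (background, LA, or the image border); the chain is ordered by
#' Moore-neighbour tracing with 8-connectivity.
#'
#' @param slice a [lax_slice()].
#' @return n x 2 integer matrix of (row, col) pixel indices, ordered and
#'   closed (last connects back to first); attribute `n_components` records
#'   how many LV components the slice contained.
#' @export
extract_lv_boundary <- function(slice) {
  stopifnot(inherits(slice, "lax_slice"))
  mask <- slice$labels == 1L
  if (!any(mask)) stop("slice contains no LV pixels")
  mask <- largest_component_mask(mask)
  ncomp <- attr(mask, "n_components")
  chain <- moore_trace(mask)
  # restrict to 4-boundary pixels (diagonal-only contacts are traced through
  # but are interior under the 4-neighbour boundary definition)
  b4 <- boundary4(mask)
  keep <- b4[cbind(chain[, 1], chain[, 2])]
  chain <- chain[keep, , drop = FALSE]
  # drop consecutive duplicates (possible at 1-px-wide spurs)
  if (nrow(chain) > 1L) {
    dup <- c(FALSE, rowSums(abs(diff(chain))) == 0)
    chain <- chain[!dup, , drop = FALSE]
  }
  attr(chain, "n_components") <- ncomp
  chain
}

#' Identify the mitral-valve interface on an LV boundary chain
#'
#' The LA segmentation marks the mitral valve: boundary pixels with at least
#' one LA pixel in their 8-neighbourhood belong to the LV/LA interface and
#' are excluded from the endocardial perimeter.
#'
#' @param slice a [lax_slice()].
#' @param boundary chain from [extract_lv_boundary()] on the same slice.
#' @return integer vector of chain indices at the interface (may be empty
#'   when the slice contains no LA; downstream measurements then flag the
#'   view non-compliant and use the closed contour).
#' @export
mv_interface <- function(slice, boundary) {
  stopifnot(inherits(slice, "lax_slice"))
  la <- slice$labels == 2L
  if (!any(la)) return(integer(0))
  nr <- nrow(la); nc <- ncol(la)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- la
  near_la <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    near_la <- near_la | pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  which(near_la[cbind(boundary[, 1], boundary[, 2])])
}

polyline_length <- function(pts, closed = FALSE) {
  if (nrow(pts) < 2L) return(0)
  L <- sum(sqrt(rowSums(diff(pts)^2)))
  if (closed) L <- L + sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
  L
}

chain_to_mm <- function(chain, spacing) {
  cbind(x = (chain[, 1] - 1) * spacing, y = (chain[, 2] - 1) * spacing)
}

# Remove the mitral run from a cyclic chain, returning the open ordered index
# sequence. The chain is rotated to start just after the largest removed run;
# stray interface pixels outside that run are dropped and their neighbours
# joined directly.
open_chain_at_mv <- function(n, mv_idx) {
  if (length(mv_idx) == 0L) return(list(idx = seq_len(n), closed = TRUE))
  keep <- setdiff(seq_len(n), mv_idx)
  if (length(keep) == 0L) stop("entire boundary lies on the mitral interface")
  rem <- sort(mv_idx)
  # cyclic gaps between consecutive removed indices; the largest removed run
  # is the maximal cyclic stretch of consecutive removed indices
  is_rem <- logical(n); is_rem[rem] <- TRUE
  # find run starts in cyclic order
  starts <- rem[!is_rem[(rem - 2L) %% n + 1L]]
  if (length(starts) == 0L) starts <- rem[1]  # fully removed handled above
  run_len <- vapply(starts, function(s) {
    l <- 0L; i <- s
    while (is_rem[i]) { l <- l + 1L; i <- i %% n + 1L; if (l > n) break }
    l
  }, integer(1))
  s <- starts[which.max(run_len)]
  first_keep <- (s + run_len[which.max(run_len)] - 1L) %% n + 1L
  ord <- ((first_keep - 1L) + 0:(n - 1L)) %% n + 1L
  list(idx = ord[!is_rem[ord]], closed = FALSE)
}

new_endo_contour <- function(points, method, closed, compliant, fallback = FALSE) {
  structure(list(points = points, method = method,
                 length_mm = polyline_length(points, closed = closed),
                 closed = closed, compliant = compliant, fallback = fallback),
            class = "endo_contour")
}

#' @export
print.endo_contour <- function(x, ...) {
  cat(sprintf("endo_contour [%s]: %d points, length %.2f mm%s%s\n",
              x$method, nrow(x$points), x$length_mm,
              if (x$closed) " (closed)" else "",
              if (!x$compliant) " [non-compliant: no mitral interface]" else ""))
  invisible(x)
}

#' Naive endocardial perimeter (method A)
#'
#' Converts the LV boundary chain to a polyline through pixel centres (mm)
#' and removes the mitral-interface run to open the contour. No smoothing of
#' any kind is applied: diagonal chain steps contribute `sqrt(2)` times the
#' pixel spacing, so the raw perimeter carries both the papillary-indentation
#' excess and the digitisation bias of the segmentation.
#'
#' @param slice a [lax_slice()].
#' @return An `endo_contour` (`method = "naive"`) with the open polyline, its
#'   length in mm, and `compliant = FALSE` when the slice has no LA (the
#'   closed contour is then measured instead).
#' @export
perimeter_naive <- function(slice) {
  chain <- extract_lv_boundary(slice)
  mv <- mv_interface(slice, chain)
  op <- open_chain_at_mv(nrow(chain), mv)
  pts <- chain_to_mm(chain, slice$spacing)[op$idx, , drop = FALSE]
  new_endo_contour(pts, "naive", closed = op$closed, compliant = !op$closed)
}

close_mask <- function(mask, disk_radius) {
  if (disk_radius <= 0) return(mask)
  kern <- EBImage::makeBrush(2L * as.integer(disk_radius) + 1L, shape = "disc")
  # pad so dilation is not clipped at image borders
  p <- as.integer(disk_radius) + 1L
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2L * p, nc + 2L * p)
  pad[(p + 1):(p + nr), (p + 1):(p + nc)] <- mask
  cl <- EBImage::closing(pad, kern)
  matrix(cl[(p + 1):(p + nr), (p + 1):(p + nc)] > 0.5, nr, nc)
}

# rasterise the convex hull of a mask's boundary pixels back onto the pixel
# grid: a pixel belongs to the hull mask when its centre lies inside (or on)
# the hull polygon. Degenerate hulls (< 3 vertices, collinear) return the
# mask unchanged.
convex_hull_mask <- function(mask) {
  b <- which(boundary4(mask), arr.ind = TRUE)
  if (nrow(b) < 3L) return(mask)
  h <- grDevices::chull(b)
  if (length(h) < 3L) return(mask)
  poly <- b[h, , drop = FALSE]  # chull order is clockwise in (row, col)
  nr <- nrow(mask); nc <- ncol(mask)
  xy_r <- rep(seq_len(nr), nc)
  xy_c <- rep(seq_len(nc), each = nr)
  inside <- rep(TRUE, nr * nc)
  np <- nrow(poly)
  for (i in seq_len(np)) {
    p1 <- poly[i, ]; p2 <- poly[i %% np + 1L, ]
    cr <- (p2[1] - p1[1]) * (xy_c - p1[2]) - (p2[2] - p1[2]) * (xy_r - p1[1])
    inside <- inside & (cr <= 1e-9)
  }
  matrix(inside, nr, nc)
}

# ordered boundary chain (4-boundary pixels, Moore-traced) of a binary mask
trace_chain <- function(mask) {
  chain <- moore_trace(mask)
  b4 <- boundary4(mask)
  keep <- b4[cbind(chain[, 1], chain[, 2])]
  chain <- chain[keep, , drop = FALSE]
  if (nrow(chain) > 1L) {
    dup <- c(FALSE, rowSums(abs(diff(chain))) == 0)
    chain <- chain[!dup, , drop = FALSE]
  }
  chain
}

# open boundary chain (mm) of the convex-hull corrected LV mask, with the
# mitral run removed; shared by the hull and spline perimeter methods
lv_hull_chain <- function(slice, disk_radius = 10L) {
  mask <- slice$labels == 1L
  if (!any(mask)) stop("slice contains no LV pixels")
  mask <- largest_component_mask(mask)
  hmask <- convex_hull_mask(close_mask(mask, disk_radius))
  chain <- trace_chain(hmask)
  mv <- mv_interface(slice, chain)
  op <- open_chain_at_mv(nrow(chain), mv)
  list(points = chain_to_mm(chain, slice$spacing)[op$idx, , drop = FALSE],
       closed = op$closed, compliant = !op$closed)
}

#' Convex-hull corrected perimeter (method B)
#'
#' Bridges papillary-muscle indentations: the LV mask is morphologically
#' closed with a disk structuring element (default radius 10 pixels), its
#' boundary is replaced by the filled convex hull, and the resulting mask's
#' boundary chain is measured with the same pixel-centre chain metric as the
#' naive method (the mitral run again removed to open the contour). The
#' convexification removes papillary notches, but the measurement still
#' carries the digitisation and surface-texture inflation of a pixel chain.
#'
#' The structuring-element radius is in pixels, so the physical smoothing
#' scale depends on the reslicing pixel spacing.
#'
#' @param slice a [lax_slice()].
#' @param disk_radius radius of the disk structuring element in pixels.
#' @return An `endo_contour` (`method = "hull"`).
#' @export
perimeter_hull <- function(slice, disk_radius = 10L) {
  stopifnot(inherits(slice, "lax_slice"))
  hc <- lv_hull_chain(slice, disk_radius)
  new_endo_contour(hc$points, "hull", closed = hc$closed, compliant = hc$compliant)
}

# natural cubic spline through 2D knots, parameterised by cumulative chord
# length, zero second derivative at both ends; arc length by dense sampling
natural_spline_curve <- function(knots, samples_per_knot = 20L) {
  tt <- c(0, cumsum(sqrt(rowSums(diff(knots)^2))))
  fx <- stats::splinefun(tt, knots[, 1], method = "natural")
  fy <- stats::splinefun(tt, knots[, 2], method = "natural")
  ts <- seq(0, tt[length(tt)],
            length.out = max(samples_per_knot * nrow(knots), 200L))
  cbind(x = fx(ts), y = fy(ts))
}

#' Natural-spline smoothed perimeter (method C)
#'
#' Suppresses endocardial surface texture and chain digitisation bias: the
#' open hull-corrected boundary chain is downsampled by keeping every
#' `downsample`-th pixel (both mitral endpoints always retained), and a
#' natural cubic spline (zero second derivative at the open ends) is fit
#' through the retained points, parameterised by cumulative chord length.
#' The perimeter is the spline's arc length evaluated by dense sampling
#' (at least 20 samples per knot).
#'
#' @param slice a [lax_slice()].
#' @param disk_radius disk radius (pixels) for the underlying hull step.
#' @param downsample keep every k-th chain pixel before fitting (default 5).
#' @return An `endo_contour` (`method = "spline"`). When fewer than 8 points
#'   survive downsampling the hull contour is returned unchanged with
#'   `fallback = TRUE` and a warning.
#' @export
perimeter_spline <- function(slice, disk_radius = 10L, downsample = 5L) {
  stopifnot(inherits(slice, "lax_slice"))
  hc <- lv_hull_chain(slice, disk_radius)
  pts <- hc$points
  if (hc$closed) pts <- rbind(pts, pts[1, ])  # traverse the closed chain once
  n <- nrow(pts)
  keep <- unique(c(seq(1L, n, by = as.integer(downsample)), n))
  if (length(keep) < 8L) {
    warning("fewer than 8 points after downsampling: falling back to hull perimeter")
    return(new_endo_contour(hc$points, "spline", closed = hc$closed,
                            compliant = hc$compliant, fallback = TRUE))
  }
  sp <- natural_spline_curve(pts[keep, , drop = FALSE])
  new_endo_contour(sp, "spline", closed = FALSE, compliant = hc$compliant)
}

#' Measure all perimeter methods on one slice
#'
#' @param slice a [lax_slice()].
#' @param methods subset of `c("naive", "hull", "spline")`.
#' @param disk_radius,downsample see [perimeter_hull()] and
#'   [perimeter_spline()].
#' @return named list of `endo_contour` objects.
#' @export
measure_perimeters <- function(slice, methods = c("naive", "hull", "spline"),
                               disk_radius = 10L, downsample = 5L) {
  methods <- match.arg(methods, c("naive", "hull", "spline"), several.ok = TRUE)
  out <- list()
  if ("naive" %in% methods) out$naive <- perimeter_naive(slice)
  if ("hull" %in% methods) out$hull <- perimeter_hull(slice, disk_radius)
  if ("spline" %in% methods) out$spline <- perimeter_spline(slice, disk_radius, downsample)
  out
}

#' LV cavity area of a slice
#'
#' Raw LV pixel count times pixel area (mm^2); feeds fractional area change.
#' @param slice a [lax_slice()].
#' @return area in mm^2.
#' @export
slice_lv_area <- function(slice) {
  stopifnot(inherits(slice, "lax_slice"))
  sum(slice$labels == 1L) * slice$spacing^2
}
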