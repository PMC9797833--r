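#' Specification of a synthetic left-heart phantom
#'
#' Describes a contracting ellipsoidal LV blood pool with an attached LA,
#' optional papillary-muscle indentations, endocardial surface texture, and
#' an optional regional (sector-wise) contraction deficit. The phantom is the
#' package's ground-truth test bed: every stochastic element is fixed by
#' `seed`, and the smooth (papillary-free, texture-free) geometry admits
#' analytic perimeters, strain, fractional area change and ejection fraction.
#'
#' Geometry: the LV long axis is the z axis of the world frame (mm, origin at
#' the grid centre). The LV cavity at end-diastole is the ellipsoid with
#' semi-axes `lv_semi_axes` cut by the flat mitral plane; the LA sits above
#' that plane and does not move. Contraction scales the LV about the point
#' where the long axis pierces the mitral plane, so the mitral plane stays
#' fixed in the LV frame and the smooth contour of every long-axis view
#' scales exactly by the phase scale factor.
#'
#' @param grid_shape integer vector of 3, voxels per axis.
#' @param spacing isotropic voxel spacing in mm.
#' @param lv_semi_axes LV end-diastolic semi-axes (a, b, c) in mm; c is the
#'   long-axis semi-axis.
#' @param la_semi_axes LA semi-axes in mm.
#' @param n_phases number of cardiac phases (reconstructions at equal
#'   fractions of the R-R interval); at least 2.
#' @param s_es linear scale factor at end-systole (`s = 1` at end-diastole);
#'   `0 < s_es <= 1`.
#' @param scale_profile optional numeric vector of per-phase linear scale
#'   factors overriding the default raised-sine profile
#'   `s_k = 1 - (1 - s_es) * sin(pi k / K)^2`, k = 0..K-1 (end-systole at
#'   phase `K/2`).
#' @param papillary list with `count` (number of indentations; 0 disables),
#'   `depth` (inward indentation depth, mm) and `width_deg` (angular width of
#'   each indentation as seen from the long axis, degrees).
#' @param texture list describing the endocardial surface irregularity, with
#'   two components. Shape texture: `amplitude` (RMS radial perturbation in
#'   mm; 0 disables), `n_modes` (random angular Fourier modes), `max_freq`
#'   (highest angular frequency, setting the correlation scale) and `drift`
#'   (radians of pattern drift per phase step; default 0 keeps the pattern
#'   fixed on the surface). Segmentation jitter: `jitter_amp` (RMS amplitude
#'   in mm of a fine-scale, per-frame-independent boundary perturbation
#'   emulating frame-to-frame noise of automated blood-pool segmentations;
#'   0 disables) and `jitter_freq` (angular frequency range of the jitter
#'   modes). Perturbation amplitudes are held constant in mm, so texture
#'   becomes relatively coarser as the cavity contracts.
#' @param abnormal `NULL` for a uniformly contracting LV, or a list with
#'   `center_deg` (azimuth of the hypokinetic sector centre; use
#'   [view_azimuths()] to target a view), `width_deg` (sector width) and
#'   `delta_s` (end-systolic scale deficit: inside the sector the
#'   end-systolic scale becomes `min(1, s_es + delta_s)`).
#' @param seed integer seed fixing all stochastic elements.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         spacing = 1.25,
                         lv_semi_axes = c(24, 24, 38),
                         la_semi_axes = c(21, 21, 16),
                         n_phases = 10L,
                         s_es = 0.8,
                         scale_profile = NULL,
                         papillary = list(count = 2L, depth = 6, width_deg = 40),
                         texture = list(amplitude = 0.8, n_modes = 6L, max_freq = 7L, drift = 0,
                                        jitter_amp = 0.5, jitter_freq = c(25L, 50L)),
                         abnormal = NULL,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(spacing) == 1L, spacing > 0,
            length(lv_semi_axes) == 3L, all(lv_semi_axes > 0),
            length(la_semi_axes) == 3L, all(la_semi_axes > 0),
            n_phases >= 2L, s_es > 0, s_es <= 1)
  if (is.null(scale_profile)) {
    k <- seq_len(n_phases) - 1L
    scale_profile <- 1 - (1 - s_es) * sin(pi * k / n_phases)^2
  }
  stopifnot(length(scale_profile) == n_phases,
            all(scale_profile > 0), all(scale_profile <= 1))
  papillary <- utils::modifyList(list(count = 2L, depth = 6, width_deg = 40), papillary)
  texture <- utils::modifyList(list(amplitude = 0.8, n_modes = 6L, max_freq = 7L,
                                    drift = 0, jitter_amp = 0.5,
                                    jitter_freq = c(25L, 50L)), texture)
  if (!is.null(abnormal)) {
    abnormal <- utils::modifyList(list(center_deg = 0, width_deg = 90, delta_s = 0.2), abnormal)
    stopifnot(abnormal$delta_s >= 0)
  }
  structure(list(
    grid_shape = grid_shape, spacing = spacing,
    lv_semi_axes = lv_semi_axes, la_semi_axes = la_semi_axes,
    n_phases = as.integer(n_phases), s_es = s_es,
    scale_profile = scale_profile,
    papillary = papillary, texture = texture,
    abnormal = abnormal, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Standard long-axis view azimuths used by the phantom
#'
#' Azimuths (degrees about the LV long axis) at which the generated 4CH, 3CH
#' and 2CH plane definitions are placed.
#' @return Named numeric vector.
#' @export
view_azimuths <- function() c("4CH" = 0, "3CH" = 60, "2CH" = 120)

# internal layout derived from a phantom_spec: LV centre, mitral plane height,
# LA centre (all mm, world frame). The mitral plane cuts the LV ellipsoid at
# 68% of its long semi-axis above centre.
phantom_layout <- function(spec) {
  c_lv <- spec$lv_semi_axes[3]
  lv_center <- c(0, 0, -0.2 * c_lv)
  z_mv <- lv_center[3] + 0.68 * c_lv
  # LA centre sits close to the mitral plane so the atrium is wider than the
  # mitral orifice everywhere above it: the LA then marks the whole basal LV
  # cap as valve at every phase, keeping mitral-segment removal consistent
  # between end-diastole and end-systole
  la_center <- c(0, 0, z_mv + 0.25 * spec$la_semi_axes[3])
  list(lv_center = lv_center, z_mv = z_mv, la_center = la_center)
}

# seeded stochastic elements: texture Fourier modes and papillary placement.
# RNG state of the caller is preserved.
phantom_draws <- function(spec) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  tx <- spec$texture
  nm <- tx$n_modes
  amp_coef <- stats::rnorm(nm)
  amp_coef <- amp_coef / sqrt(sum(amp_coef^2) / 2)  # unit RMS of the mode sum
  modes <- list(
    a = amp_coef,
    m = sample(2:tx$max_freq, nm, replace = TRUE),    # azimuthal frequency
    n = sample(1:tx$max_freq, nm, replace = TRUE),    # polar frequency
    ph = stats::runif(nm, 0, 2 * pi),
    drift = stats::runif(nm, -1, 1) * tx$drift        # rad per phase step
  )
  # fine-scale per-frame segmentation jitter: same mode shapes every frame,
  # independent random phases per frame (so frames decorrelate)
  jitter <- NULL
  if (tx$jitter_amp > 0) {
    nj <- 4L
    ja <- stats::rnorm(nj)
    ja <- ja / sqrt(sum(ja^2) / 2)
    jitter <- list(
      a = ja,
      m = sample(tx$jitter_freq[1]:tx$jitter_freq[2], nj, replace = TRUE),
      n = sample(2:6, nj, replace = TRUE),
      ph = matrix(stats::runif(nj * 40L, 0, 2 * pi), nj, 40L)  # per-phase phases
    )
  }
  # heart orientation about the long axis relative to the voxel grid:
  # patients are not scanner-aligned, so no view plane is grid-aligned
  orientation_deg <- stats::runif(1, 0, 360)
  np <- spec$papillary$count
  pap <- NULL
  if (np > 0) {
    # azimuths in the view frame, uniform: any long-axis view can be affected
    pap <- list(
      azimuth_deg = stats::runif(np, 0, 360),
      z_frac = stats::runif(np, -0.25, 0.05)  # polar height on unit ellipsoid
    )
  }
  list(modes = modes, jitter = jitter, papillary = pap,
       orientation_deg = orientation_deg)
}

# effective per-phase scale inside the hypokinetic sector: the contraction
# excursion is shrunk so the end-systolic scale is s_es + delta_s.
abnormal_scale <- function(spec, s_normal) {
  ab <- spec$abnormal
  if (is.null(ab) || ab$delta_s <= 0) return(s_normal)
  s_es_ab <- min(1, spec$s_es + ab$delta_s)
  rho <- if (spec$s_es >= 1) 0 else (1 - s_es_ab) / (1 - spec$s_es)
  1 - rho * (1 - s_normal)
}

ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# papillary bite spheres at one phase: centre on the (scaled) endocardial
# surface moved outward so a spherical cap of the requested depth is bitten
# inward; radius follows from depth and angular width. Azimuths are in the
# view frame; the heart's grid orientation is added for world positions.
papillary_spheres <- function(spec, draws, lay, s_at_az) {
  pap <- draws$papillary
  if (is.null(pap)) return(NULL)
  ax <- spec$lv_semi_axes
  d <- spec$papillary$depth
  halfw <- spec$papillary$width_deg * pi / 360
  out <- vector("list", length(pap$azimuth_deg))
  for (i in seq_along(pap$azimuth_deg)) {
    phi <- (pap$azimuth_deg[i] + draws$orientation_deg) * pi / 180
    cth <- pap$z_frac[i]
    sth <- sqrt(max(0, 1 - cth^2))
    q <- c(sth * cos(phi), sth * sin(phi), cth)      # unit-sphere point
    w <- lay$lv_center + ax * q                      # ED surface point
    r_loc <- sqrt(sum((ax * q)^2))
    L <- r_loc * sin(halfw)
    rho <- (L^2 + d^2) / (2 * d)
    s <- s_at_az(pap$azimuth_deg[i])
    p <- c(0, 0, lay$z_mv)
    w_s <- p + s * (w - p)                           # surface point at this phase
    n_out <- q / ax; n_out <- n_out / sqrt(sum(n_out^2))
    out[[i]] <- list(center = w_s + (rho - d) * n_out, radius = rho)
  }
  out
}

#' Generate a synthetic cine left-heart phantom
#'
#' Renders the label volumes (0 = background, 1 = LV blood pool, 2 = LA blood
#' pool) for every cardiac phase, the three long-axis plane definitions, and
#' the analytic ground truth of the smooth geometry.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `ct_phantom` with elements `cine` (a
#'   [cine_segmentation()]), `planes` (list of [plane_definition()]), `truth`
#'   (class `phantom_truth`: per-view/per-phase smooth perimeters in mm, true
#'   LS, FAC, EF, ED/ES phase indices and abnormality flags) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lay <- phantom_layout(spec)
  draws <- phantom_draws(spec)
  ax <- spec$lv_semi_axes
  la <- spec$la_semi_axes
  dims <- spec$grid_shape
  sp <- spec$spacing
  half <- (dims - 1) / 2 * sp
  amp <- spec$texture$amplitude + spec$texture$jitter_amp

  if (prod(ax) <= 0) stop("degenerate (zero-volume) LV")

  # feasibility: scaled LV + texture and the LA must fit strictly inside
  for (k in seq_len(spec$n_phases)) {
    s <- spec$scale_profile[k]
    ext_xy <- max(ax[1], ax[2]) * s + amp
    apex_z <- lay$z_mv + s * ((lay$lv_center[3] - ax[3]) - lay$z_mv) - amp
    if (ext_xy > half[1] || ext_xy > half[2] || apex_z < -half[3])
      stop(sprintf("phantom geometry exceeds grid at phase %d", k))
  }
  if (la[1] > half[1] || la[2] > half[2] || lay$la_center[3] + la[3] > half[3])
    stop("phantom geometry exceeds grid at phase 1 (left atrium)")

  # world coordinates of voxel centres (grid centre at origin)
  xs <- (seq_len(dims[1]) - 1) * sp - half[1]
  ys <- (seq_len(dims[2]) - 1) * sp - half[2]
  zs <- (seq_len(dims[3]) - 1) * sp - half[3]
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)

  # azimuth in the view frame (heart orientation removed)
  az_deg <- (atan2(Y, X) * 180 / pi - draws$orientation_deg) %% 360
  in_sector <- if (!is.null(spec$abnormal))
    ang_diff(az_deg, spec$abnormal$center_deg) <= spec$abnormal$width_deg / 2
  else array(FALSE, dims)

  la_mask <- ((X / la[1])^2 + (Y / la[2])^2 + ((Z - lay$la_center[3]) / la[3])^2 <= 1) &
    (Z >= lay$z_mv)

  modes <- draws$modes
  s_at_az_factory <- function(s_n, s_a) function(az)
    ifelse(ang_diff(az, if (is.null(spec$abnormal)) 0 else spec$abnormal$center_deg) <=
             (if (is.null(spec$abnormal)) -1 else spec$abnormal$width_deg / 2), s_a, s_n)

  frames <- vector("list", spec$n_phases)
  for (k in seq_len(spec$n_phases)) {
    s_n <- spec$scale_profile[k]
    s_a <- abnormal_scale(spec, s_n)
    s_vox <- ifelse(in_sector, s_a, s_n)

    # un-scale about the mitral-plane/long-axis intersection point
    q1 <- (X / s_vox) / ax[1]
    q2 <- (Y / s_vox) / ax[2]
    q3 <- ((lay$z_mv + (Z - lay$z_mv) / s_vox) - lay$lv_center[3]) / ax[3]
    u <- sqrt(q1^2 + q2^2 + q3^2)

    tx_amp <- spec$texture$amplitude
    j_amp <- spec$texture$jitter_amp
    if (tx_amp > 0 || j_amp > 0) {
      theta <- acos(pmin(1, pmax(-1, q3 / pmax(u, 1e-12))))
      phi <- atan2(q2, q1)
      f <- 0
      if (tx_amp > 0) {
        for (j in seq_along(modes$a))
          f <- f + tx_amp * modes$a[j] * cos(modes$m[j] * phi + modes$n[j] * theta +
                                               modes$ph[j] + modes$drift[j] * (k - 1))
      }
      if (j_amp > 0) {
        jt <- draws$jitter
        col <- (k - 1L) %% ncol(jt$ph) + 1L
        for (j in seq_along(jt$a))
          f <- f + j_amp * jt$a[j] * cos(jt$m[j] * phi + jt$n[j] * theta +
                                           jt$ph[j, col])
      }
      r_loc <- sqrt((ax[1] * q1)^2 + (ax[2] * q2)^2 + (ax[3] * q3)^2) / pmax(u, 1e-12)
      delta_u <- f / (r_loc * s_vox)
    } else delta_u <- 0

    lv <- (u <= 1 + delta_u) & (Z < lay$z_mv)

    sph <- papillary_spheres(spec, draws, lay, s_at_az_factory(s_n, s_a))
    if (!is.null(sph)) for (b in sph)
      lv <- lv & ((X - b$center[1])^2 + (Y - b$center[2])^2 +
                    (Z - b$center[3])^2 >= b$radius^2)

    lab <- array(0L, dims)
    lab[lv] <- 1L
    lab[la_mask & !lv] <- 2L
    frames[[k]] <- lab
  }

  origin <- -half
  cine <- cine_segmentation(frames, spacing = rep(sp, 3), origin = origin,
                            phase_pct = (seq_len(spec$n_phases) - 1) * 100 / spec$n_phases)

  vaz <- view_azimuths()
  planes <- lapply(names(vaz), function(v) {
    phi <- (vaz[[v]] + draws$orientation_deg) * pi / 180
    plane_definition(v, origin = c(0, 0, 0),
                     x_dir = c(cos(phi), sin(phi), 0), y_dir = c(0, 0, 1))
  })
  names(planes) <- names(vaz)

  truth <- phantom_truth(spec, lay)
  structure(list(cine = cine, planes = planes, truth = truth, spec = spec,
                 draws = draws, layout = lay),
            class = "ct_phantom")
}

# Analytic ground truth of the smooth (papillary- and texture-free) geometry.
# Per-view contours are densely sampled ellipse arcs below the mitral plane,
# scaled point-wise by the sector-dependent phase scale; perimeters, areas,
# LS and FAC follow from the polylines, EF from an azimuthal quadrature of
# the wedge-wise volume scaling (wedge weight proportional to the squared
# cross-radius).
phantom_truth <- function(spec, lay = phantom_layout(spec)) {
  ax <- spec$lv_semi_axes
  vaz <- view_azimuths()
  K <- spec$n_phases
  ed <- which.max(spec$scale_profile)[1]
  es <- which.min(spec$scale_profile)[1]
  m <- (lay$z_mv - lay$lv_center[3]) / ax[3]
  t1 <- pi - asin(m)
  t2 <- 2 * pi + asin(m)
  tt <- seq(t1, t2, length.out = 4001)

  s_of <- function(az_deg, k) {
    s_n <- spec$scale_profile[k]
    if (is.null(spec$abnormal)) return(rep(s_n, length(az_deg)))
    s_a <- abnormal_scale(spec, s_n)
    ifelse(ang_diff(az_deg, spec$abnormal$center_deg) <= spec$abnormal$width_deg / 2,
           s_a, s_n)
  }

  perim <- matrix(NA_real_, length(vaz), K, dimnames = list(names(vaz), NULL))
  area <- matrix(NA_real_, length(vaz), K, dimnames = list(names(vaz), NULL))
  for (vi in seq_along(vaz)) {
    phiv <- vaz[[vi]]
    r_phi <- 1 / sqrt(cos(phiv * pi / 180)^2 / ax[1]^2 + sin(phiv * pi / 180)^2 / ax[2]^2)
    u0 <- r_phi * cos(tt)
    v0 <- lay$lv_center[3] + ax[3] * sin(tt)
    az_pt <- ifelse(u0 >= 0, phiv, phiv + 180)
    for (k in seq_len(K)) {
      s_pt <- s_of(az_pt, k)
      us <- u0 * s_pt
      vs <- lay$z_mv + (v0 - lay$z_mv) * s_pt
      perim[vi, k] <- sum(sqrt(diff(us)^2 + diff(vs)^2))
      # cavity area: arc closed by the mitral chord (shoelace)
      px <- c(us, us[1]); py <- c(vs, vs[1])
      area[vi, k] <- abs(sum(px[-1] * py[-length(py)] - px[-length(px)] * py[-1])) / 2
    }
  }

  ls <- (perim[, es] - perim[, ed]) / perim[, ed]
  fac <- (area[, ed] - area[, es]) / area[, ed]

  # EF: wedge volumes scale by s(phi)^3, wedge weight ~ cross-radius^2
  phis <- seq(0, 2 * pi, length.out = 1441)[-1441]
  w <- 1 / (cos(phis)^2 / ax[1]^2 + sin(phis)^2 / ax[2]^2)
  vfrac <- function(k) {
    s3 <- s_of(phis * 180 / pi, k)^3
    sum(w * s3) / sum(w)
  }
  ef <- 1 - vfrac(es) / vfrac(ed)

  abn_views <- vapply(names(vaz), function(v) {
    if (is.null(spec$abnormal)) return(FALSE)
    any(ang_diff(c(vaz[[v]], vaz[[v]] + 180), spec$abnormal$center_deg) <=
          spec$abnormal$width_deg / 2)
  }, logical(1))

  structure(list(
    perimeter = perim, area = area, ls = ls, fac = fac, ef = ef,
    ed_phase = ed, es_phase = es,
    abnormal_views = abn_views, abnormal_study = any(abn_views)
  ), class = "phantom_truth")
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat("ct_phantom:", x$spec$n_phases, "phases on",
      paste(x$spec$grid_shape, collapse = "x"), "grid @",
      x$spec$spacing, "mm\n")
  cat("  truth LS:", paste(sprintf("%s %.3f", names(x$truth$ls), x$truth$ls),
                           collapse = ", "), "\n")
  cat("  truth EF:", sprintf("%.3f", x$truth$ef),
      if (x$truth$abnormal_study) " (regional abnormality present)" else "", "\n")
  invisible(x)
}

#' Draw a seeded population of phantom specifications
#'
#' Produces `n` phantom specs with per-study variation of contractility,
#' papillary-indentation depth and surface-texture amplitude, optionally with
#' a regionally hypokinetic subgroup. Used for population-level validation of
#' the perimeter methods and the cutoff-selection machinery.
#'
#' @param n number of phantoms.
#' @param seed population seed; phantom `i` receives seed `seed * 1000 + i`
#'   for its own stochastic elements.
#' @param grid_shape,spacing grid passed to every spec (defaults trade
#'   resolution for throughput in population runs).
#' @param s_es_range range of end-systolic scale factors (uniform draw).
#' @param papillary_depth_range,texture_amp_range uniform ranges, mm.
#' @param p_abnormal probability that a study carries a hypokinetic sector.
#' @param delta_s end-systolic scale deficit of the sector.
#' @param abnormal_width_deg sector width, degrees.
#' @return list of `phantom_spec` objects.
#' @export
phantom_population <- function(n, seed = 1L,
                               grid_shape = c(80L, 80L, 80L), spacing = 1.5,
                               s_es_range = c(0.55, 0.95),
                               papillary_depth_range = c(4, 8),
                               texture_amp_range = c(0.5, 1.2),
                               p_abnormal = 0, delta_s = 0.2,
                               abnormal_width_deg = 90) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  vaz <- view_azimuths()
  lapply(seq_len(n), function(i) {
    s_es <- stats::runif(1, s_es_range[1], s_es_range[2])
    ab <- NULL
    if (stats::runif(1) < p_abnormal) {
      ab <- list(center_deg = unname(sample(vaz, 1)),
                 width_deg = abnormal_width_deg, delta_s = delta_s)
    }
    phantom_spec(
      grid_shape = grid_shape, spacing = spacing, s_es = s_es,
      papillary = list(count = 2L,
                       depth = stats::runif(1, papillary_depth_range[1], papillary_depth_range[2]),
                       width_deg = 40),
      texture = list(amplitude = stats::runif(1, texture_amp_range[1], texture_amp_range[2]),
                     n_modes = 6L, max_freq = 7L),
      abnormal = ab,
      seed = seed * 1000L + i
    )
  })
}
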