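test_that("static and uniformly contracting phantoms have analytic truth", {
  # no deformation: all phases identical, zero strain everywhere
  sp0 <- small_phantom_spec(seed = 1, scale_profile = rep(1, 4), n_phases = 4L,
                            papillary = list(count = 0L),
                            texture = list(amplitude = 0, jitter_amp = 0))
  ph0 <- generate_phantom(sp0)
  expect_identical(ph0$cine$frames[[1]], ph0$cine$frames[[3]])
  expect_equal(unname(ph0$truth$ls), rep(0, 3))

  # uniform isotropic contraction to s = 0.8
  sp1 <- small_phantom_spec(seed = 1, s_es = 0.8,
                            papillary = list(count = 0L),
                            texture = list(amplitude = 0, jitter_amp = 0))
  ph1 <- generate_phantom(sp1)
  expect_equal(unname(ph1$truth$ls), rep(-0.2, 3), tolerance = 1e-6)
  expect_equal(unname(ph1$truth$fac), rep(1 - 0.8^2, 3), tolerance = 1e-6)
  expect_equal(ph1$truth$ef, 1 - 0.8^3, tolerance = 1e-6)
  # truth perimeters scale exactly with s
  expect_equal(ph1$truth$perimeter[, ph1$truth$es_phase],
               0.8 * ph1$truth$perimeter[, ph1$truth$ed_phase], tolerance = 1e-9)
})

test_that("generation is deterministic in the seed", {
  a <- generate_phantom(small_phantom_spec(seed = 7))
  b <- generate_phantom(small_phantom_spec(seed = 7))
  expect_identical(a$cine$frames, b$cine$frames)
  c <- generate_phantom(small_phantom_spec(seed = 8))
  expect_false(identical(a$cine$frames, c$cine$frames))
})

test_that("labels partition the grid and LV/LA touch only at the mitral plane", {
  ph <- generate_phantom(small_phantom_spec(seed = 4))
  z_mv <- ph$layout$z_mv
  sp <- ph$spec$spacing
  half <- (ph$spec$grid_shape - 1) / 2 * sp
  for (k in c(1L, ph$truth$es_phase)) {
    f <- ph$cine$frames[[k]]
    expect_true(all(f %in% c(0L, 1L, 2L)))
    # face contacts between LV and LA
    lv <- f == 1L; la <- f == 2L
    d <- dim(f)
    # x and y direction face contacts must not exist
    expect_false(any(lv[-d[1], , ] & la[-1, , ]) || any(lv[-1, , ] & la[-d[1], , ]))
    expect_false(any(lv[, -d[2], ] & la[, -1, ]) || any(lv[, -1, ] & la[, -d[2], ]))
    # z contacts allowed, but only across the mitral plane
    up <- which(lv[, , -d[3]] & la[, , -1], arr.ind = TRUE)
    if (nrow(up) > 0) {
      z_lv <- (up[, 3] - 1) * sp - half[3]
      expect_true(all(z_lv < z_mv & z_lv + sp >= z_mv - 1e-9))
    }
    expect_false(any(lv[, , -1] & la[, , -d[3]]))  # LA never below LV
  }
})

test_that("papillary indentations inflate the naive perimeter of the ED slice", {
  spc <- phantom_spec(grid_shape = c(96L, 96L, 96L), spacing = 1.25, seed = 5,
                      papillary = list(count = 2L, depth = 6, width_deg = 50),
                      texture = list(amplitude = 0))
  ph <- generate_phantom(spc)
  # pick the view whose plane passes nearest a papillary azimuth
  pap_az <- ph$draws$papillary$azimuth_deg %% 360
  vaz <- view_azimuths()
  dist_to_view <- sapply(vaz, function(a)
    min(abs(((pap_az - c(a, a + 180)) + 180) %% 360 - 180)))
  v <- names(which.min(dist_to_view))
  sl <- reslice(ph$cine, ph$planes[[v]], phase = ph$truth$ed_phase,
                pixel_spacing = 0.5)
  pn <- perimeter_naive(sl)
  truth_ed <- ph$truth$perimeter[v, ph$truth$ed_phase]
  expect_gt(pn$length_mm, truth_ed)
  # independent oracle: EBImage's own contour tracer on the same mask
  mask <- ctstrain:::largest_component_mask(sl$labels == 1L)
  oc <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask)))[[1]]
  oracle_len <- ctstrain:::polyline_length(oc * sl$spacing, closed = TRUE)
  naive_closed <- ctstrain:::polyline_length(
    ctstrain:::chain_to_mm(ctstrain:::trace_chain(mask), sl$spacing), closed = TRUE)
  expect_equal(naive_closed, oracle_len, tolerance = 0.02)
})

test_that("halving the grid at double spacing leaves truth unchanged and measurements close", {
  fine <- generate_phantom(phantom_spec(grid_shape = c(96L, 96L, 96L), spacing = 1.25,
                                        seed = 3, papillary = list(count = 0L),
                                        texture = list(amplitude = 0, jitter_amp = 0)))
  coarse <- generate_phantom(phantom_spec(grid_shape = c(48L, 48L, 48L), spacing = 2.5,
                                          seed = 3, papillary = list(count = 0L),
                                          texture = list(amplitude = 0, jitter_amp = 0)))
  expect_equal(fine$truth$perimeter, coarse$truth$perimeter, tolerance = 1e-12)
  slf <- reslice(fine$cine, fine$planes[["4CH"]], phase = 1, pixel_spacing = 0.5)
  slc <- reslice(coarse$cine, coarse$planes[["4CH"]], phase = 1, pixel_spacing = 0.5)
  # measured perimeters at the two renderings agree to the coarse-grid scale
  # (rendering plus valve-margin quantisation each contribute ~1 voxel)
  diag_coarse <- sqrt(2) * 2.5
  expect_lt(abs(perimeter_spline(slf)$length_mm - perimeter_spline(slc)$length_mm),
            2 * diag_coarse)
})

test_that("regional hypokinesis reduces strain only in the targeted view", {
  spc <- small_phantom_spec(seed = 6, papillary = list(count = 0L),
                            texture = list(amplitude = 0),
                            abnormal = list(center_deg = unname(view_azimuths()["2CH"]),
                                            width_deg = 90, delta_s = 0.2))
  ph <- generate_phantom(spc)
  expect_identical(unname(ph$truth$abnormal_views), c(FALSE, FALSE, TRUE))
  expect_true(ph$truth$abnormal_study)
  # 2CH strain magnitude strictly reduced, other views at the nominal value
  expect_gt(ph$truth$ls["2CH"], -0.2 + 0.04)
  expect_equal(unname(ph$truth$ls[c("4CH", "3CH")]), rep(-0.2, 2), tolerance = 1e-6)
  # the measured pipeline sees it too
  res <- run_study(ph$cine, ph$planes, strain_config(all_phases = FALSE))
  tab <- res$table[res$table$method == "spline", ]
  expect_gt(tab$ls[tab$view == "2CH"], max(tab$ls[tab$view != "2CH"]) + 0.02)
})

test_that("impossible geometries are rejected with the offending phase", {
  expect_error(generate_phantom(phantom_spec(grid_shape = c(48L, 48L, 48L),
                                             spacing = 1,
                                             lv_semi_axes = c(30, 30, 40))),
               "phase 1")
  expect_error(phantom_spec(lv_semi_axes = c(0, 24, 38)))
  expect_error(phantom_spec(s_es = 0))
  expect_error(phantom_spec(n_phases = 1L))
})

test_that("phantom population draws are seed-stable and honour the abnormal rate", {
  p1 <- phantom_population(10, seed = 5, p_abnormal = 0.5)
  p2 <- phantom_population(10, seed = 5, p_abnormal = 0.5)
  expect_identical(p1, p2)
  ab <- vapply(p1, function(s) !is.null(s$abnormal), logical(1))
  expect_true(any(ab) && !all(ab))
  s_es <- vapply(p1, function(s) s$s_es, numeric(1))
  expect_true(all(s_es >= 0.55 & s_es <= 0.95))
})
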