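test_that("pupil segmentation closes the glint hole and gates degenerate input", {
  crop <- pupil_crop(render_scene(noise_sigma = 0))
  m <- segment_pupil(crop)
  true_area <- pi * 36 * 34
  expect_lt(abs(sum(m) - true_area) / true_area, 0.02)
  # glint pixels sit inside the closed mask
  expect_true(m[41, 47])  # glint center (310,228) in crop coordinates
  expect_error(segment_pupil(matrix(128, 60, 60)), "no pupil pixels")
})

test_that("star rays cover both flank windows and respect circle geometry", {
  # 2-degree steps over two closed 130-degree windows: 66 + 66 = 132 rays
  crop <- pupil_crop(render_scene(noise_sigma = 0))
  pts <- star_ray_edges(crop)
  expect_equal(nrow(pts), 132)
  # perfect circle: every edge point lies at radius r from the center
  circ <- render_scene(pupil_axes = c(30, 30), glint_offsets = list(c(-8, -9)),
                       noise_sigma = 0)
  cc <- pupil_crop(circ)
  pc <- star_ray_edges(cc)
  radii <- sqrt((pc[, 1] - 56)^2 + (pc[, 2] - 52)^2)
  expect_lt(max(abs(radii - 30)), 0.5)
  expect_error(star_ray_edges(crop, seed_point = c(56, 52),
                              config = feature_config(
                                ray_windows = list(c(0, 4)))),
               "insufficient edge support")
})

test_that("occluded frames keep their edge support on the flanks", {
  # half-occluded pupil: the windows plus lid-line rejection keep enough
  # lateral support for the fit to succeed
  crop <- pupil_crop(render_scene(eyelid_coverage = 0.5, noise_sigma = 0))
  m <- segment_pupil(crop)
  pts <- star_ray_edges(crop, m)
  expect_gt(nrow(pts), 30)
  fit <- fit_ellipse(pts)
  expect_lt(abs(fit$center[1] - 56), 1.5)
})

test_that("direct ellipse fit is exact on noiseless samples", {
  pts <- ellipse_points(c(50, 40), c(30, 20), 25, n = 20)
  f <- fit_ellipse(pts)
  expect_equal(f$center, c(50, 40), tolerance = 1e-8)
  expect_equal(f$axes, c(30, 20), tolerance = 1e-8)
  expect_equal(f$angle, 25, tolerance = 1e-6)
  # circle: orientation undefined, returned as a = b, angle 0
  fc <- fit_ellipse(ellipse_points(c(10, 10), c(5, 5), 0, n = 12))
  expect_equal(fc$axes[1], fc$axes[2])
  expect_equal(fc$angle, 0)
  expect_error(fit_ellipse(ellipse_points(c(0, 0), c(3, 2), 0, n = 5)),
               "6 points")
  line <- cbind(x = 1:10, y = 2 * (1:10) + 1)
  expect_error(fit_ellipse(line))
})

test_that("glint centroiding is sub-pixel accurate and flags blinks", {
  crop <- pupil_crop(render_scene(noise_sigma = 0))
  g <- glint_center(crop)
  expect_false(g$missing)
  expect_lt(sqrt(sum((g$center - c(46, 40))^2)), 0.3)
  # symmetric square glint: centroid is the exact geometric center
  sq <- matrix(50, 40, 40)
  sq[18:21, 24:27] <- 255
  gs <- glint_center(sq, config = feature_config(glint_min_level = 200))
  expect_equal(gs$center, c(24.5, 18.5))
  # blink frame (no glint rendered): missing flag, no bogus centroid
  blink <- pupil_crop(render_scene(glint_offsets = list(c(500, 500)),
                                   noise_sigma = 0))
  gb <- glint_center(blink)
  expect_true(gb$missing)
  expect_true(all(is.na(gb$center)))
})

test_that("the PCR vector is a plain difference and translation invariant", {
  e <- list(center = c(100, 90))
  expect_equal(pcr_vector(e, c(90, 78)), c(10, 12))
  expect_equal(pcr_vector(e, c(100, 90)), c(0, 0))
  # translating the whole scene leaves the vector unchanged
  o1 <- extract_observation(pupil_crop(render_scene(noise_sigma = 0)))
  img2 <- render_scene(pupil_center = c(327, 245), noise_sigma = 0)
  o2 <- extract_observation(pupil_crop(img2, center = c(327, 245)))
  expect_equal(c(o2$vx, o2$vy), c(o1$vx, o1$vy), tolerance = 0.1)
})

test_that("flank-window fit agrees with an all-boundary fit when unoccluded", {
  crop <- pupil_crop(render_scene(noise_sigma = 0))
  m <- segment_pupil(crop)
  full <- fit_ellipse(star_ray_edges(crop, m,
                                     config = feature_config(
                                       ray_windows = list(c(0, 358)))))
  flank <- fit_ellipse(star_ray_edges(crop, m))
  expect_lt(max(abs(full$center - flank$center)), 0.2)
})

test_that("extract_observation reports occlusion against a reference area", {
  cfgf <- feature_config()
  full_area <- sum(segment_pupil(pupil_crop(render_scene(noise_sigma = 0))))
  occ <- pupil_crop(render_scene(eyelid_coverage = 0.5, noise_sigma = 0))
  ob <- extract_observation(occ, cfgf, ref_area = full_area)
  expect_true(ob$occluded)
  ob2 <- extract_observation(pupil_crop(render_scene(noise_sigma = 0)),
                             cfgf, ref_area = full_area)
  expect_false(ob2$occluded)
  expect_true(ob2$valid)
})
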