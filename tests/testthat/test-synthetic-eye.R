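test_that("noiseless rendering places exact intensities and records truth", {
  r <- render_eye_frame(eye_scene_params(noise_sigma = 0))
  expect_equal(dim(r$image), c(480, 640))
  # interior pupil pixel is exactly the pupil gray level
  expect_identical(r$image[241, 321], 30)
  # glint core saturates at the glint gray level
  expect_identical(r$image[229, 311], 250)
  expect_equal(r$truth$pupil_center, c(320, 240))
  expect_equal(r$truth$pcr, c(10, 12))
  # intensity ordering holds on interior masks (eroded away from boundaries)
  xs <- matrix(0:639, 480, 640, byrow = TRUE); ys <- matrix(0:479, 480, 640)
  d2 <- ((xs - 320) / 36)^2 + ((ys - 240) / 34)^2
  glint_d <- sqrt((xs - 310)^2 + (ys - 228)^2)
  pupil_in <- d2 < 0.9 & glint_d > 5
  iris_in <- d2 > 1.2 & sqrt((xs - 320)^2 + (ys - 240)^2) < 100
  sclera_in <- sqrt((xs - 320)^2 + (ys - 240)^2) > 120
  expect_true(max(r$image[pupil_in]) < min(r$image[iris_in]))
  expect_true(max(r$image[iris_in]) < min(r$image[sclera_in]))
  expect_true(max(r$image[sclera_in]) < 250)
})

test_that("eyelid occlusion clips the pupil from the top", {
  r <- render_eye_frame(eye_scene_params(eyelid_coverage = 0.5))
  # coverage 0.5 puts the lid at the horizontal line through the center:
  # no pupil-intensity pixels above it
  expect_false(any(r$image[1:240, ] == 30))
  # visible pupil remains below
  expect_true(any(r$image[242:480, ] == 30))
  # the glint above the clip line is occluded
  expect_length(r$truth$glints, 0)
  expect_true(all(is.na(r$truth$pcr)))
})

test_that("rendering is deterministic and invalid scenes are rejected", {
  p <- eye_scene_params(noise_sigma = 3, seed = 42)
  expect_identical(render_eye_frame(p)$image, render_eye_frame(p)$image)
  p2 <- eye_scene_params(noise_sigma = 3, seed = 43)
  expect_false(identical(render_eye_frame(p)$image, render_eye_frame(p2)$image))
  expect_error(eye_scene_params(pupil_center = c(10, 240)), "out of frame")
  expect_error(eye_scene_params(pupil_axes = c(0, 10)), "degenerate")
  expect_error(eye_scene_params(pupil_intensity = 200), "ordering")
})

test_that("calibration grid follows the margin formula and clips corners", {
  g <- make_calibration_grid(c(1280, 720), 0.1)
  expect_equal(nrow(g), 9)
  expect_equal(unlist(g[g$point == 1, c("sx", "sy")], use.names = FALSE),
               c(128, 72))
  expect_equal(unlist(g[g$point == 5, c("sx", "sy")], use.names = FALSE),
               c(640, 360))
  expect_equal(unlist(g[g$point == 9, c("sx", "sy")], use.names = FALSE),
               c(1152, 648))
  g0 <- make_calibration_grid(c(1280, 720), 0)
  expect_equal(unlist(g0[g0$point == 1, c("sx", "sy")], use.names = FALSE),
               c(0, 0))
  expect_equal(unlist(g0[g0$point == 9, c("sx", "sy")], use.names = FALSE),
               c(1279, 719))
  expect_equal(nrow(unique(g[, c("sx", "sy")])), 9)
  expect_error(make_calibration_grid(c(0, 720)), "positive")
})

test_that("trajectories have the advertised structure", {
  g <- make_calibration_grid(c(1280, 720), 0.1)
  fx <- make_fixation_trajectory(g, 5)
  expect_equal(nrow(fx), 45)
  expect_true(all(diff(fx$frame) == 1))
  expect_equal(length(unique(fx$point)), 9)

  pu <- make_pursuit_trajectory(pursuit_point_order(g), dwell_frames = 4,
                                motion_frames = 3)
  expect_equal(length(unique(pu$period)), 19)  # 10 dwells + 9 moves
  expect_equal(sum(pu$phase == "fixation"), 10 * 4)
  expect_equal(sum(pu$phase == "pursuit"), 9 * 3)
  expect_true(all(pu$sx >= 0 & pu$sx <= 1280 & pu$sy >= 0 & pu$sy <= 720))

  # constant-velocity construction: speed (20, 10) px/s at 1 fps gives
  # POR differences of exactly (20, 10) within a pursuit segment
  tp <- data.frame(point = 1:2, sx = c(100, 200), sy = c(100, 150))
  pv <- make_pursuit_trajectory(tp, dwell_frames = 2, speed = c(20, 10),
                                fps = 1)
  seg <- pv[pv$phase == "pursuit", ]
  expect_equal(unique(round(diff(seg$sx), 10)), 20)
  expect_equal(unique(round(diff(seg$sy), 10)), 10)
  expect_error(make_pursuit_trajectory(tp[0, ], 2, 2), "empty")
})

test_that("rendered sequences agree with their ground truth by construction", {
  g <- make_calibration_grid(c(1280, 720), 0.1)
  imap <- default_inverse_map(c(1280, 720))
  traj <- make_fixation_trajectory(g[c(1, 5, 9), ], 2)
  sim <- render_sequence(traj, imap, eye_scene_params(noise_sigma = 0))
  expect_length(sim$frames, nrow(traj))
  # ground-truth PCR equals the generator map of the POR (zero jitter)
  v <- pcr_from_por(imap, traj$sx, traj$sy)
  expect_equal(sim$truth$vx, v[, "vx"])
  expect_equal(sim$truth$vy, v[, "vy"])
  # PCR is pupil minus glint
  expect_equal(sim$truth$px - sim$truth$gx, sim$truth$vx)
  expect_equal(sim$truth$py - sim$truth$gy, sim$truth$vy)
  # stationary trajectory, zero jitter: all PCR vectors identical
  st <- make_fixation_trajectory(g[5, ], 4)
  sim2 <- render_sequence(st, imap, eye_scene_params(noise_sigma = 0))
  expect_equal(length(unique(sim2$truth$vx)), 1)
  expect_error(render_sequence(traj[0, ], imap, eye_scene_params()), "empty")
})

test_that("parameter-level streams carry slippage and noise as specified", {
  g <- make_calibration_grid(c(1280, 720), 0.1)
  imap <- default_inverse_map(c(1280, 720))
  traj <- make_fixation_trajectory(g, 10)
  s0 <- simulate_pcr_stream(traj, imap, noise_sd = 0)
  expect_equal(s0$vx, s0$true_vx)
  s1 <- simulate_pcr_stream(traj, imap, noise_sd = 0.3,
                            pcr_offset = c(1, -2), seed = 7)
  expect_equal(s1$true_vx - s0$true_vx, rep(1, nrow(s1)))
  expect_equal(s1$true_vy - s0$true_vy, rep(-2, nrow(s1)))
  expect_equal(stats::sd(s1$vx - s1$true_vx), 0.3, tolerance = 0.15)
  expect_identical(s1$vx,
                   simulate_pcr_stream(traj, imap, noise_sd = 0.3,
                                       pcr_offset = c(1, -2), seed = 7)$vx)
})

test_that("frames survive a PNG round trip", {
  dir <- withr::local_tempdir()
  frames <- list(render_scene(noise_sigma = 2, seed = 1),
                 render_scene(noise_sigma = 2, seed = 2))
  write_frames_png(frames, dir)
  back <- read_frames_png(dir)
  expect_length(back, 2)
  expect_equal(back[[1]], frames[[1]])
  expect_equal(back[[2]], frames[[2]])
})
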