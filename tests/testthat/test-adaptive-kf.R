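test_that("prediction applies the kinematic model", {
  mod <- kf_model("cv")
  st <- kf_init_state(c(10, 20), mod)
  st$x <- c(10, 20, 2, -1)
  pr <- kf_predict(st, mod)
  expect_equal(pr$x, c(12, 19, 2, -1))
  # A = I, Q = 0 leaves the covariance untouched
  mod0 <- kf_model("cv", q = 0)
  mod0$A <- diag(4)
  st2 <- kf_init_state(c(0, 0), mod0)
  expect_equal(kf_predict(st2, mod0)$P, st2$P)
  # zero velocity: position unchanged under CV
  stz <- kf_init_state(c(5, 6), mod)
  expect_equal(kf_predict(stz, mod)$x[1:2], c(5, 6))
})

test_that("correction limits and the scalar closed form hold", {
  mod <- kf_model("cv")
  st <- kf_predict(kf_init_state(c(0, 0), mod), mod)
  # R -> 0: full trust in the measurement
  c0 <- kf_correct(st, c(5, 7), mod, R = 1e-15)
  expect_equal(c0$x[1:2], c(5, 7), tolerance = 1e-9)
  # R -> infinity: gain vanishes, state equals the prediction
  cI <- kf_correct(st, c(5, 7), mod, R = 1e12)
  expect_equal(cI$x, st$x, tolerance = 1e-6)
  # scalar analogue: P_pred = 1, R = 1 gives K = 1/2 and the midpoint
  stm <- st
  stm$x <- c(0, 0, 0, 0)
  stm$P <- diag(c(1, 1, 0, 0))
  cm <- kf_correct(stm, c(4, -2), mod, R = 1)
  expect_equal(cm$K[1, 1], 0.5)
  expect_equal(cm$x[1:2], c(2, -1))
  # singular innovation covariance is refused
  sts <- stm; sts$P <- matrix(0, 4, 4)
  expect_error(kf_correct(sts, c(0, 0), mod, R = 0), "singular")
})

test_that("missing-measurement steps are exactly the prediction recursion", {
  mod <- kf_model("cv")
  st <- kf_init_state(c(3, 4), mod)
  st$x <- c(3, 4, 1, 2)
  a <- kf_step_missing(st, mod)
  b <- kf_predict(st, mod)
  expect_identical(a$x, b$x)
  expect_identical(a$P, b$P)
  # five missing frames extrapolate linearly
  s <- st
  for (i in 1:5) s <- kf_step_missing(s, mod)
  expect_equal(s$x[1:2], c(3 + 5 * 1, 4 + 5 * 2))
  # covariance keeps growing while measurements are absent
  expect_gt(s$P[1, 1], st$P[1, 1])
})

test_that("eye difference is a motion-energy proxy", {
  a <- matrix(0.5, 10, 10)
  expect_equal(eye_difference(a, a), 0)
  b <- a; b[3, 3] <- b[3, 3] + 1
  expect_equal(eye_difference(b, a), 1)
  expect_error(eye_difference(a, matrix(0, 5, 5)), "shape")
  # monotone in pupil displacement on rendered crops
  base <- pupil_crop(render_scene(noise_sigma = 0)) / 255
  ms <- vapply(c(1, 3, 8, 20), function(d) {
    shifted <- pupil_crop(render_scene(pupil_center = c(320 + d, 240),
                                       noise_sigma = 0),
                          center = c(320, 240)) / 255
    eye_difference(shifted, base)
  }, 0)
  expect_true(all(ms > 0))
  expect_true(all(diff(ms) > 0))
})

test_that("logistic gate and gated velocity follow their formulas", {
  expect_equal(logistic_gate(2, alpha_m = 2, beta_m = 1), 0.5)
  expect_equal(logistic_gate(4, alpha_m = 2, beta_m = 1),
               1 / (1 + exp(-2)))
  expect_lt(logistic_gate(0, alpha_m = 50, beta_m = 1), 1e-6)
  expect_error(logistic_gate(1, 1, 0), "positive")
  expect_equal(gaze_velocity(1, c(3, 4), c(3, 4)), c(0, 0))
  expect_equal(gaze_velocity(1, c(3, 4), c(0, 0)), c(3, 4))
  expect_equal(gaze_velocity(0.5, c(2, 0), c(0, 0)), c(1, 0))
})

test_that("measurement-noise adaptation rises fast and decays slowly", {
  cfg <- adaptive_config(R_max = 0.04, R_min = 4e-4, w_R = 0.3)
  # floor holds at zero speed
  expect_equal(update_R(cfg$R_min, 0, cfg), cfg$R_min)
  # speed burst: instant rise to R_max
  expect_equal(update_R(cfg$R_min, c(0, 0, 1), cfg), cfg$R_max)
  # speeds drop to zero: geometric decay R <- 0.7 R_prev each step
  R <- cfg$R_max
  for (i in 1:5) {
    R_next <- update_R(R, 0, cfg)
    expect_equal(R_next, max(0.7 * R, cfg$R_min))
    R <- R_next
  }
  # inverse adaptation flag flips the speed relation
  cfg_inv <- adaptive_config(inverse_adaptation = TRUE)
  expect_equal(update_R(cfg_inv$R_min, 1, cfg_inv), cfg_inv$R_min)
  expect_equal(update_R(cfg_inv$R_min, 0, cfg_inv), cfg_inv$R_max)
})

test_that("filtering a stream starts at the raw value and smooths noise", {
  set.seed(9)
  n <- 500
  obs <- data.frame(frame = 0:(n - 1),
                    vx = 10 + rnorm(n), vy = -5 + rnorm(n),
                    missing = FALSE)
  for (type in c("cv", "ca")) {
    f <- filter_sequence(obs, type, adaptive_config())
    # first frame: filtered equals raw exactly
    expect_identical(f$vx[1], obs$vx[1])
    expect_identical(f$vy[1], obs$vy[1])
    # white-noise input: filtered variance well below raw variance
    expect_lt(stats::var(f$vx), stats::var(obs$vx))
    expect_lt(stats::var(f$vy), stats::var(obs$vy))
  }
  # constant input with tiny Q converges to the constant
  cst <- data.frame(frame = 0:199, vx = rep(3, 200), vy = rep(-1, 200),
                    missing = FALSE)
  fc <- filter_sequence(cst, "cv", adaptive_config(),
                        model = kf_model("cv", q = 1e-12))
  expect_equal(fc$vx[200], 3, tolerance = 1e-6)
  # leading missing frames are waited out
  miss <- obs
  miss$missing[1:3] <- TRUE
  fm <- filter_sequence(miss, "cv", adaptive_config())
  expect_true(all(is.na(fm$vx[1:3])))
  expect_identical(fm$vx[4], obs$vx[4])
})

test_that("with adaptation disabled the filter equals a textbook KF", {
  set.seed(4)
  n <- 300
  z <- cbind(rnorm(n, 2, 0.5), rnorm(n, -3, 0.5))
  obs <- data.frame(frame = 0:(n - 1), vx = z[, 1], vy = z[, 2],
                    missing = FALSE)
  R_const <- 0.02
  cfg <- adaptive_config(R_max = R_const, R_min = R_const)
  for (type in c("cv", "ca")) {
    mod <- kf_model(type)
    f <- filter_sequence(obs, type, cfg, model = mod)
    x0 <- numeric(mod$dim); x0[1:2] <- z[1, ]
    P0 <- diag(mod$dim); P0[1, 1] <- P0[2, 2] <- R_const
    ref <- textbook_kf(z, mod$A, mod$H, mod$Q, R_const, x0, P0)
    expect_lt(max(abs(f$vx - ref[, 1])), 1e-10)
    expect_lt(max(abs(f$vy - ref[, 2])), 1e-10)
  }
})

test_that("the state covariance stays symmetric positive semi-definite", {
  set.seed(2)
  mod <- kf_model("ca")
  st <- kf_init_state(c(0, 0), mod)
  cfg <- adaptive_config()
  R <- cfg$R_min
  worst <- Inf
  for (i in 1:10000) {
    st <- kf_predict(st, mod)
    R <- update_R(R, runif(1), cfg)
    if (i %% 7 == 0) {
      st <- kf_step_missing(st, mod)
    } else {
      st <- kf_correct(st, rnorm(2), mod, R = R)
    }
    if (i %% 250 == 0) {
      expect_equal(st$P, t(st$P))
      worst <- min(worst, min(eigen(st$P, symmetric = TRUE,
                                    only.values = TRUE)$values))
    }
  }
  expect_gt(worst, -1e-9)
})

test_that("published compatibility forms are available behind flags", {
  m4 <- kf_model("ca", printed_ca = TRUE)
  expect_equal(dim(m4$A), c(4, 4))
  expect_equal(m4$A[1, 4], 0.5)   # the printed x <- x + dT vx + dT^2/2 vy row
  mh <- kf_model("cv", printed_h = TRUE)
  expect_equal(mh$H, matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 2, 4, byrow = TRUE))
  m6 <- kf_model("ca")
  expect_equal(dim(m6$A), c(6, 6))
  expect_equal(m6$A[1, 5], 0.5)
  expect_equal(m6$A[3, 5], 1)
})
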