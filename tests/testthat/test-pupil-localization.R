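test_that("pupil detection finds the dark blob and rejects implausible ones", {
  img <- render_scene(noise_sigma = 0)
  box <- detect_pupil(img)
  ctr <- c(box$x + (box$width - 1) / 2, box$y + (box$height - 1) / 2)
  expect_lt(sqrt(sum((ctr - c(320, 240))^2)), 2)
  # box tightly matches the 72 x 68 pupil
  expect_equal(box$width, 71, tolerance = 2)
  expect_equal(box$height, 67, tolerance = 2)
  # all-white frame: nothing to detect
  expect_error(detect_pupil(matrix(255, 120, 160)), "pupil not found")
  # two dark blobs, one tiny: the larger plausible one wins
  two <- matrix(200, 200, 200)
  two[80:120, 80:130] <- 20    # 41 x 51 blob
  two[10:12, 10:12] <- 20      # tiny speck
  b2 <- detect_pupil(two, threshold = 100, area_range = c(50, 10000))
  expect_equal(c(b2$x, b2$y), c(79, 79))
  expect_equal(c(b2$width, b2$height), c(51, 41))
})

test_that("box expansion preserves the center and clips at borders", {
  b <- expand_box(bounding_box(100, 100, 80, 80), 1.25)
  expect_equal(c(b$x, b$y, b$width, b$height), c(90, 90, 100, 100))
  b1 <- expand_box(bounding_box(100, 100, 80, 80), 1.0)
  expect_equal(c(b1$x, b1$y, b1$width, b1$height), c(100, 100, 80, 80))
  # near the origin the expanded box is truncated, shifting its center inward
  bc <- expand_box(bounding_box(2, 2, 40, 40), 1.5, image_size = c(640, 480))
  expect_equal(c(bc$x, bc$y), c(0, 0))
  expect_lt(bc$width, 60)
  expect_error(expand_box(bounding_box(0, 0, 10, 10), 0.5), ">= 1")
  expect_error(bounding_box(0, 0, 0, 10), "positive")
})

test_that("kernel correlation matches the brute-force cyclic-shift oracle", {
  set.seed(7)
  for (sz in list(c(8, 8), c(8, 12))) {
    x <- matrix(rnorm(prod(sz)), sz[1], sz[2])
    z <- matrix(rnorm(prod(sz)), sz[1], sz[2])
    k <- kernel_correlation(x, z, sigma = 0.5)
    expect_lt(max(abs(k - brute_kernel(x, z, 0.5))), 1e-10)
    expect_true(all(k > 0 & k <= 1))
  }
  # self-correlation: zero shift cancels exactly to exp(0) = 1
  x <- matrix(rnorm(64), 8, 8)
  ks <- kernel_correlation(x, x, 0.2)
  expect_equal(ks[1, 1], 1)
  expect_equal(max(ks), ks[1, 1])
  # zero patches: all distances vanish, all entries 1
  expect_equal(kernel_correlation(x * 0, x * 0, 0.2),
               matrix(1, 8, 8))
  expect_error(kernel_correlation(x, x, 0), "positive")
  expect_error(kernel_correlation(x, matrix(0, 4, 4), 1), "shape")
})

test_that("FFT dual solution equals explicit circulant ridge regression", {
  set.seed(3)
  n <- 16
  lambda <- 1e-4; sigma <- 0.2
  x <- matrix(rnorm(n * n) * 0.2, n, n)
  y <- gazefilter:::gaussian_target(c(n, n), 2)
  k <- kernel_correlation(x, x, sigma)
  alpha_fft <- Re(gazefilter:::ifft2(gazefilter:::fft2(y) /
                                       (gazefilter:::fft2(k) + lambda)))
  # oracle: build the full 256 x 256 circulant kernel matrix from explicit
  # shifts and solve the ridge system directly
  kb <- brute_kernel(x, x, sigma)
  N <- n * n
  idx <- expand.grid(iy = 0:(n - 1), ix = 0:(n - 1))
  K <- matrix(0, N, N)
  for (i in seq_len(N)) {
    dy <- (idx$iy - idx$iy[i]) %% n
    dx <- (idx$ix - idx$ix[i]) %% n
    K[i, ] <- kb[cbind(dy + 1, dx + 1)]
  }
  alpha_exact <- solve(K + lambda * diag(N), as.vector(y))
  expect_lt(max(abs(as.vector(alpha_fft) - alpha_exact)), 1e-8)
})

test_that("tracker initialization peaks on itself and respects the rate", {
  img <- render_scene(noise_sigma = 0)
  box <- expand_box(detect_pupil(img), 1.25, c(640, 480))
  st <- kcf_init(img, box, kcf_config())
  tr <- kcf_track(st, img)
  # same frame: zero displacement, response peak at zero shift
  expect_equal(tr$state$center, st$center, tolerance = 1e-6)
  expect_gt(tr$peak_value, 0.95)
  # learning rate ~0 leaves the model numerically unchanged
  st0 <- kcf_init(img, box, kcf_config(eta = 1e-12))
  tr0 <- kcf_track(st0, img)
  expect_equal(tr0$state$alpha_hat, st0$alpha_hat, tolerance = 1e-9)
  expect_equal(tr0$state$template, st0$template, tolerance = 1e-9)
  expect_error(kcf_init(img, bounding_box(0, 0, 4, 4)), "too small")
})

test_that("a translated pupil is recovered within a pixel", {
  f1 <- render_scene(noise_sigma = 0)
  f2 <- render_scene(pupil_center = c(325, 237), noise_sigma = 0)
  box <- expand_box(detect_pupil(f1), 1.25, c(640, 480))
  st <- kcf_init(f1, box, kcf_config())
  tr <- kcf_track(st, f2)
  expect_lt(max(abs((tr$state$center - st$center) - c(5, -3))), 1)
})

test_that("response peak degrades under additive noise at fixed shift", {
  f1 <- render_scene(noise_sigma = 0)
  box <- expand_box(detect_pupil(f1), 1.25, c(640, 480))
  peaks <- vapply(c(0, 4, 12), function(ns) {
    med <- stats::median(vapply(1:5, function(s) {
      f2 <- render_scene(pupil_center = c(323, 238), noise_sigma = ns,
                         seed = s)
      st <- kcf_init(f1, box, kcf_config())
      kcf_track(st, f2)$peak_value
    }, 0))
    med
  }, 0)
  expect_true(all(diff(peaks) <= 0))
})

test_that("track_sequence follows motion and re-detects when asked", {
  ctrs <- walk_centers(12)
  frames <- lapply(seq_len(nrow(ctrs)), function(i)
    render_scene(pupil_center = ctrs[i, ], noise_sigma = 0))
  trk <- track_sequence(frames)
  err <- sqrt((trk$cx - ctrs[, 1])^2 + (trk$cy - ctrs[, 2])^2)
  expect_lt(max(err), 3)
  expect_true(all(diff(trk$frame) == 1))
  expect_error(track_sequence(list()), "no frames")
})
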