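# Shared fixtures: all imagery is generated in code, nothing is stored.

`%||%` <- function(a, b) if (is.null(a)) b else a

render_scene <- function(...) render_eye_frame(eye_scene_params(...))$image

# Pupil-region crop as the tracker would hand it to feature extraction:
# centered on the (true) pupil center, 1.25x the pupil box plus margin.
pupil_crop <- function(img, center = c(320, 240), size = c(105, 113)) {
  gazefilter:::get_subwindow(img, center, size)
}

crop_offset <- function(center = c(320, 240), size = c(105, 113)) {
  c(round(center[1]) - floor(size[2] / 2), round(center[2]) - floor(size[1] / 2))
}

# Cyclic 2-D shift of a matrix by (dy, dx): entry (i, j) of the result is
# m[(i - dy) mod h, (j - dx) mod w]. Used by the brute-force kernel oracle.
cyclic_shift <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

# Brute-force Gaussian kernel vector over all cyclic shifts (the independent
# oracle for kernel_correlation): explicit shifting, no FFT.
brute_kernel <- function(x, z, sigma) {
  h <- nrow(x); w <- ncol(x)
  k <- matrix(0, h, w)
  for (dy in 0:(h - 1)) {
    for (dx in 0:(w - 1)) {
      d2 <- sum((x - cyclic_shift(z, dy, dx))^2) / length(x)
      k[dy + 1, dx + 1] <- exp(-d2 / sigma^2)
    }
  }
  k
}

# A simple textbook constant-R Kalman filter, written independently of the
# package's implementation, as the oracle for the constant-R equivalence.
textbook_kf <- function(z, A, H, Q, R, x0, P0) {
  n <- nrow(z)
  out <- matrix(NA_real_, n, length(x0))
  x <- x0; P <- P0
  out[1, ] <- x
  for (i in 2:n) {
    x <- A %*% x
    P <- A %*% P %*% t(A) + Q
    P <- (P + t(P)) / 2
    S <- H %*% P %*% t(H) + R * diag(2)
    K <- P %*% t(H) %*% solve(S)
    x <- x + K %*% (z[i, ] - H %*% x)
    P <- (diag(length(x0)) - K %*% H) %*% P
    P <- (P + t(P)) / 2
    out[i, ] <- x
  }
  out
}

# Random-walk pupil-center trajectory with bounded per-frame steps.
walk_centers <- function(n, step_x = 8, step_y = 6, seed = 11) {
  set.seed(seed)
  steps <- cbind(stats::runif(n - 1, -step_x, step_x),
                 stats::runif(n - 1, -step_y, step_y))
  ctrs <- rbind(c(320, 240),
                sweep(apply(steps, 2, cumsum), 2, c(320, 240), `+`))
  ctrs[, 1] <- pmin(pmax(ctrs[, 1], 160), 480)
  ctrs[, 2] <- pmin(pmax(ctrs[, 2], 150), 330)
  ctrs
}
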