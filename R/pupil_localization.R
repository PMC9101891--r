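# Pupil localization: intensity-based detection in the first frame, then
# kernelized correlation-filter (KCF) tracking with raw grayscale features.
#
# The tracker learns a ridge regression over all cyclic shifts of a windowed
# grayscale template. Because the data matrix of cyclic shifts is circulant,
# it is diagonalized by the DFT and the dual (kernel-space) solution is
# alpha_hat = y_hat / (k_hat + lambda), where k is the first row of the
# Gaussian kernel matrix, itself computable with two FFTs. Detection evaluates
# the learned filter on the shifted search window and takes the response peak
# as the displacement; the model is then updated by linear interpolation with
# learning rate eta.

#' Bounding box constructor
#'
#' @param x,y top-left corner, 0-based pixels.
#' @param width,height box size in pixels (> 0).
#' @return list of class `bounding_box`.
#' @export
bounding_box <- function(x, y, width, height) {
  if (width <= 0 || height <= 0) stop("box width and height must be positive")
  structure(list(x = x, y = y, width = width, height = height),
            class = "bounding_box")
}

box_center <- function(box) c(box$x + (box$width - 1) / 2,
                              box$y + (box$height - 1) / 2)

#' Expand a bounding box about its center
#'
#' Scales width and height by `factor` keeping the center fixed, then clips to
#' the image when `image_size` is given; clipping at a border truncates the
#' box, so the center may shift toward the image interior.
#'
#' @param box a [bounding_box()].
#' @param factor scale factor, >= 1 (default 1.25, which comfortably retains
#'   the corneal glints around a detected pupil).
#' @param image_size optional (width, height) for clipping.
#' @return expanded [bounding_box()].
#' @export
expand_box <- function(box, factor = 1.25, image_size = NULL) {
  if (factor < 1) stop("factor must be >= 1")
  ctr <- box_center(box)
  w <- box$width * factor
  h <- box$height * factor
  x <- ctr[1] - (w - 1) / 2
  y <- ctr[2] - (h - 1) / 2
  if (!is.null(image_size)) {
    x2 <- min(x + w, image_size[1])
    y2 <- min(y + h, image_size[2])
    x <- max(x, 0); y <- max(y, 0)
    w <- x2 - x; h <- y2 - y
  }
  bounding_box(x, y, w, h)
}

#' Detect the pupil as the largest plausible dark blob
#'
#' Thresholds the frame at a low gray level (first percentile plus an offset,
#' targeting the darkest structure in the image), labels connected components
#' and returns the bounding box of the largest component whose area and aspect
#' ratio pass plausibility gates.
#'
#' @param img grayscale frame matrix.
#' @param threshold absolute gray-level threshold; when `NULL` it is taken as
#'   `quantile(img, 0.01) + threshold_offset`.
#' @param threshold_offset gray levels added to the dark quantile.
#' @param area_range admissible blob area in pixels, `c(min, max)`.
#' @param aspect_max maximal admissible width/height (or height/width) ratio.
#' @return [bounding_box()] of the detected pupil.
#' @export
detect_pupil <- function(img, threshold = NULL, threshold_offset = 25,
                         area_range = c(200, 30000), aspect_max = 2.5) {
  if (is.null(threshold)) {
    threshold <- as.numeric(stats::quantile(img, 0.01)) + threshold_offset
  }
  mask <- img < threshold
  # a pupil is a dark minority structure; an (almost) fully dark frame has
  # no detectable pupil
  if (!any(mask) || mean(mask) > 0.9) stop("pupil not found")
  lab <- EBImage::bwlabel(mask * 1)
  tab <- tabulate(lab[lab > 0])
  ord <- order(tab, decreasing = TRUE)
  for (id in ord) {
    area <- tab[id]
    idx <- which(lab == id, arr.ind = TRUE)
    ys <- range(idx[, 1]) - 1; xs <- range(idx[, 2]) - 1
    bw <- diff(xs) + 1; bh <- diff(ys) + 1
    aspect <- max(bw / bh, bh / bw)
    if (area >= area_range[1] && area <= area_range[2] &&
        aspect <= aspect_max) {
      return(bounding_box(xs[1], ys[1], bw, bh))
    }
  }
  stop("pupil not found")
}

#' KCF tracker configuration
#'
#' Defaults are the standard raw-pixel KCF settings: ridge regularization
#' `lambda`, Gaussian kernel bandwidth `sigma` (distances are normalized by
#' the number of template pixels), model learning rate `eta`, search-window to
#' target size ratio `padding`, and the width of the Gaussian regression
#' target as a fraction of sqrt(target area).
#'
#' @param lambda ridge regularization weight (> 0).
#' @param sigma Gaussian kernel bandwidth.
#' @param eta learning rate in (0, 1).
#' @param padding search-window / target size ratio.
#' @param output_sigma_factor regression-target width factor.
#' @param confidence_threshold response-peak level below which the
#'   localization is treated as unreliable (typically a partial occlusion):
#'   the tracker then coasts -- keeps its previous center and does not update
#'   the appearance model -- until confidence returns. A well-matched target
#'   peaks near 1; occluded frames drop well below. 0 disables gating.
#' @return list of class `kcf_config`.
#' @export
kcf_config <- function(lambda = 1e-4, sigma = 0.2, eta = 0.075,
                       padding = 1.5, output_sigma_factor = 0.1,
                       confidence_threshold = 0.5) {
  stopifnot(lambda > 0, sigma > 0, eta > 0, eta < 1, padding >= 1,
            confidence_threshold >= 0, confidence_threshold < 1)
  structure(list(lambda = lambda, sigma = sigma, eta = eta,
                 padding = padding,
                 output_sigma_factor = output_sigma_factor,
                 confidence_threshold = confidence_threshold),
            class = "kcf_config")
}

# Extract an integer-aligned subwindow centered at `center` (0-based, x, y)
# of size (h, w), replicating border pixels outside the frame.
get_subwindow <- function(img, center, size_hw) {
  h <- size_hw[1]; w <- size_hw[2]
  xs <- round(center[1]) - floor(w / 2) + seq_len(w) - 1
  ys <- round(center[2]) - floor(h / 2) + seq_len(h) - 1
  xs <- pmin(pmax(xs, 0), ncol(img) - 1)
  ys <- pmin(pmax(ys, 0), nrow(img) - 1)
  img[ys + 1, xs + 1, drop = FALSE]
}

# Raw-grayscale feature patch: scale to [-0.5, 0.5] and apply a separable
# raised-cosine window to suppress boundary discontinuities under cyclic
# shifting.
preprocess_patch <- function(patch, cos_window) {
  (patch / 255 - 0.5) * cos_window
}

# Gaussian regression target with peak wrapped to index (1, 1), plus its DFT.
gaussian_target <- function(size_hw, sigma_y) {
  h <- size_hw[1]; w <- size_hw[2]
  ry <- (seq_len(h) - 1) - floor(h / 2)
  rx <- (seq_len(w) - 1) - floor(w / 2)
  g <- exp(-(outer(ry^2, rx^2, `+`)) / (2 * sigma_y^2))
  # shift the peak from the center to (1, 1)
  g <- g[c((floor(h / 2) + 1):h, seq_len(floor(h / 2))), , drop = FALSE]
  g <- g[, c((floor(w / 2) + 1):w, seq_len(floor(w / 2))), drop = FALSE]
  g
}

#' Gaussian kernel autocorrelation over all cyclic shifts
#'
#' Computes the first row of the Gaussian kernel matrix between `x` and all
#' cyclic shifts of `x_prime` in O(n log n) via the FFT:
#' `k[d] = exp(-(||x||^2 + ||x'||^2 - 2 <x, shift_d(x')>) / (sigma^2 n))`,
#' with the squared distance normalized by the number of pixels `n` so the
#' bandwidth is resolution-independent. Entries lie in (0, 1].
#'
#' @param x,x_prime preprocessed feature patches (matrices of equal dim).
#' @param sigma kernel bandwidth (> 0).
#' @return real matrix of kernel values, same dim as `x`, indexed by cyclic
#'   shift (index 1,1 = zero shift).
#' @export
kernel_correlation <- function(x, x_prime, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!all(dim(x) == dim(x_prime))) stop("patches must have identical shape")
  n <- length(x)
  cc <- Re(ifft2(fft2(x) * Conj(fft2(x_prime))))
  d2 <- pmax((sum(x^2) + sum(x_prime^2) - 2 * cc) / n, 0)
  exp(-d2 / sigma^2)
}

#' Initialize a KCF tracker on a bounding box
#'
#' Learns the initial dual filter `alpha_hat = y_hat / (k_hat + lambda)` from
#' the windowed grayscale patch covering `padding` times the target box.
#'
#' @param img grayscale frame matrix.
#' @param box target [bounding_box()].
#' @param config a [kcf_config()].
#' @return list of class `kcf_state`: `alpha_hat`, `template`, `yf`,
#'   `center`, `target_size`, `window_size`, `cos_window`, `config`,
#'   `peak_value`.
#' @export
kcf_init <- function(img, box, config = kcf_config()) {
  if (box$width < 8 || box$height < 8) stop("box too small for tracking")
  target_sz <- c(round(box$height), round(box$width))       # (h, w)
  window_sz <- round(target_sz * config$padding)
  center <- box_center(box)
  cw <- outer(hann_window(window_sz[1]), hann_window(window_sz[2]))
  patch <- preprocess_patch(get_subwindow(img, center, window_sz), cw)
  sigma_y <- config$output_sigma_factor * sqrt(prod(target_sz))
  y <- gaussian_target(window_sz, sigma_y)
  yf <- fft2(y)
  k <- kernel_correlation(patch, patch, config$sigma)
  alpha_hat <- yf / (fft2(k) + config$lambda)
  structure(list(alpha_hat = alpha_hat, template = patch, yf = yf,
                 center = center, target_size = target_sz,
                 window_size = window_sz, cos_window = cw,
                 config = config, peak_value = 1),
            class = "kcf_state")
}

# Wrap a 0-based cyclic index into a signed displacement.
wrap_disp <- function(idx0, n) ifelse(idx0 > n / 2, idx0 - n, idx0)

# Quadratic sub-pixel refinement along one axis from (f_minus, f0, f_plus).
subpixel_offset <- function(fm, f0, fp) {
  den <- 2 * f0 - fp - fm
  if (abs(den) < .Machine$double.eps) return(0)
  max(-0.5, min(0.5, 0.5 * (fp - fm) / den))
}

#' Track one frame with a KCF state
#'
#' Evaluates the filter response over the search window at the previous
#' center, moves the center by the (sub-pixel refined) response-peak
#' displacement, then updates the dual filter and template by linear
#' interpolation with the learning rate. When several response entries tie at
#' the maximum, the smallest displacement (ties broken row-major) wins.
#'
#' @param state a `kcf_state` from [kcf_init()].
#' @param img next grayscale frame.
#' @param localization_passes number of window re-centering passes (>= 1);
#'   passes after the first stop early once the residual displacement falls
#'   below a quarter pixel.
#' @return list with `box` (the tracked target [bounding_box()]), `response`
#'   (real response matrix), `peak_value`, and `state` (updated `kcf_state`).
#' @export
kcf_track <- function(state, img, localization_passes = 2) {
  cfg <- state$config
  new_center <- state$center
  response <- NULL
  mx <- NA_real_
  # The raised-cosine window attenuates content far from the window center,
  # which biases the response peak toward zero displacement; re-centering the
  # window on the first estimate and evaluating once more contracts that bias
  # quadratically.
  for (pass in seq_len(localization_passes)) {
    patch <- preprocess_patch(get_subwindow(img, new_center,
                                            state$window_size),
                              state$cos_window)
    kz <- kernel_correlation(patch, state$template, cfg$sigma)
    response <- Re(ifft2(fft2(kz) * state$alpha_hat))
    if (all(is.na(response))) stop("tracker diverged")
    h <- nrow(response); w <- ncol(response)
    mx <- max(response)
    cand <- which(response >= mx - 1e-12, arr.ind = TRUE)
    dy <- wrap_disp(cand[, 1] - 1, h)
    dx <- wrap_disp(cand[, 2] - 1, w)
    pick <- order(dy^2 + dx^2, cand[, 1], cand[, 2])[1]
    py <- cand[pick, 1]; px <- cand[pick, 2]
    # wrapped 3x3 neighbors for sub-pixel quadratic interpolation
    ym <- ((py - 2) %% h) + 1; yp <- (py %% h) + 1
    xm <- ((px - 2) %% w) + 1; xp <- (px %% w) + 1
    sub_y <- subpixel_offset(response[ym, px], response[py, px],
                             response[yp, px])
    sub_x <- subpixel_offset(response[py, xm], response[py, px],
                             response[py, xp])
    disp <- unname(c(wrap_disp(px - 1, w) + sub_x,
                     wrap_disp(py - 1, h) + sub_y))
    if (pass == 1 && mx < cfg$confidence_threshold) {
      # low-confidence match (occlusion): coast at the previous center and
      # keep the appearance model untouched
      box <- bounding_box(state$center[1] - (state$target_size[2] - 1) / 2,
                          state$center[2] - (state$target_size[1] - 1) / 2,
                          state$target_size[2], state$target_size[1])
      state$peak_value <- mx
      return(list(box = box, response = response, peak_value = mx,
                  state = state, coasting = TRUE))
    }
    new_center <- new_center + disp
    if (all(abs(disp) < 0.25)) break
  }

  new_patch <- preprocess_patch(get_subwindow(img, new_center,
                                              state$window_size),
                                state$cos_window)
  k_new <- kernel_correlation(new_patch, new_patch, cfg$sigma)
  alpha_new <- state$yf / (fft2(k_new) + cfg$lambda)
  state$alpha_hat <- (1 - cfg$eta) * state$alpha_hat + cfg$eta * alpha_new
  state$template <- (1 - cfg$eta) * state$template + cfg$eta * new_patch
  state$center <- new_center
  state$peak_value <- mx

  box <- bounding_box(new_center[1] - (state$target_size[2] - 1) / 2,
                      new_center[2] - (state$target_size[1] - 1) / 2,
                      state$target_size[2], state$target_size[1])
  list(box = box, response = response, peak_value = mx, state = state)
}

#' Track a whole frame sequence
#'
#' Detects the pupil in the first frame (unless `init_box` is supplied),
#' expands the detected box by `expand_factor` so the tracked crop retains the
#' glints, then runs the KCF frame to frame. If the response peak falls below
#' `redetect_threshold`, detection is retried once on that frame and the
#' tracker is re-initialized (an extension for recovery after appearance-
#' destroying blinks; disabled by default).
#'
#' @param frames list of grayscale frame matrices.
#' @param config a [kcf_config()].
#' @param init_box optional [bounding_box()] overriding first-frame detection.
#' @param expand_factor pupil-box expansion applied before tracking.
#' @param redetect_threshold response-peak level triggering re-detection
#'   (0 disables).
#' @return data.frame per frame: `frame`, `x`, `y`, `w`, `h`, `cx`, `cy`,
#'   `peak_value` (tracked crop box, 0-based, and its center).
#' @export
track_sequence <- function(frames, config = kcf_config(), init_box = NULL,
                           expand_factor = 1.25, redetect_threshold = 0) {
  n <- length(frames)
  if (n == 0) stop("no frames")
  img_size <- c(ncol(frames[[1]]), nrow(frames[[1]]))
  if (is.null(init_box)) init_box <- detect_pupil(frames[[1]])
  box <- expand_box(init_box, expand_factor, img_size)
  state <- kcf_init(frames[[1]], box, config)
  out <- data.frame(frame = seq_len(n) - 1L, x = NA_real_, y = NA_real_,
                    w = NA_real_, h = NA_real_, cx = NA_real_, cy = NA_real_,
                    peak_value = NA_real_)
  ctr <- box_center(box)
  out[1, 2:8] <- c(box$x, box$y, box$width, box$height, ctr[1], ctr[2], 1)
  for (i in seq_len(n)[-1]) {
    tr <- kcf_track(state, frames[[i]])
    if (redetect_threshold > 0 && tr$peak_value < redetect_threshold) {
      det <- tryCatch(detect_pupil(frames[[i]]), error = function(e) NULL)
      if (!is.null(det)) {
        box2 <- expand_box(det, expand_factor, img_size)
        state <- kcf_init(frames[[i]], box2, config)
        tr <- list(box = box2, peak_value = 1, state = state)
      }
    }
    state <- tr$state
    ctr <- box_center(tr$box)
    out[i, 2:8] <- c(tr$box$x, tr$box$y, tr$box$width, tr$box$height,
                     ctr[1], ctr[2], tr$peak_value)
  }
  out
}
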