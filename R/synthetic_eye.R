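# Synthetic infrared eye-image generator.
#
# Renders ground-truthed eye frames: a dark elliptical pupil on a brighter
# iris disc and sclera background, one or more bright corneal glints
# (Purkinje images), optional eyelid occlusion modeled as a horizontal clip
# line, and additive Gaussian sensor noise. The ellipse and glint boundaries
# are rendered with 4x4 supersampling so that sub-pixel localization is
# meaningful. Every frame carries its pre-noise ground truth.

#' Synthetic eye-scene parameters
#'
#' Bundles the geometry and photometry of a rendered eye frame. Defaults give
#' a 640x480 frame with a pupil of semi-axes (36, 34) pixels (a pupil of
#' roughly 72 x 68 pixels, typical of a close-range head-mounted eye camera)
#' and a single glint 10 px left and 12 px above the pupil center.
#'
#' @param image_size integer (width, height) in pixels.
#' @param pupil_center numeric (x, y), 0-based pixel coordinates.
#' @param pupil_axes numeric (semi-major, semi-minor) in pixels.
#' @param pupil_angle ellipse inclination, degrees (counter-clockwise from +x
#'   in display orientation with y down is clockwise on screen).
#' @param pupil_intensity,iris_intensity,sclera_intensity,glint_intensity
#'   gray levels in [0, 255]; must be strictly increasing in that order.
#' @param iris_radius iris disc radius, pixels.
#' @param glint_offsets list of numeric (dx, dy) glint centers relative to the
#'   pupil center.
#' @param glint_radius glint disc radius, pixels.
#' @param eyelid_coverage fraction in [0, 1) of the pupil height occluded by
#'   the eyelid from the top (0 = fully open eye).
#' @param eyelid_intensity gray level of the lid region.
#' @param noise_sigma additive Gaussian sensor noise, gray levels.
#' @param seed integer RNG seed used for the noise field.
#' @return object of class `eye_scene_params`.
#' @export
eye_scene_params <- function(image_size = c(640, 480),
                             pupil_center = c(320, 240),
                             pupil_axes = c(36, 34),
                             pupil_angle = 0,
                             pupil_intensity = 30,
                             iris_intensity = 90,
                             sclera_intensity = 170,
                             glint_intensity = 250,
                             iris_radius = 110,
                             glint_offsets = list(c(-10, -12)),
                             glint_radius = 3,
                             eyelid_coverage = 0,
                             eyelid_intensity = 170,
                             noise_sigma = 0,
                             seed = 1L) {
  p <- list(image_size = as.numeric(image_size),
            pupil_center = as.numeric(pupil_center),
            pupil_axes = as.numeric(pupil_axes),
            pupil_angle = as.numeric(pupil_angle),
            pupil_intensity = pupil_intensity,
            iris_intensity = iris_intensity,
            sclera_intensity = sclera_intensity,
            glint_intensity = glint_intensity,
            iris_radius = iris_radius,
            glint_offsets = if (is.list(glint_offsets)) glint_offsets
                            else list(as.numeric(glint_offsets)),
            glint_radius = glint_radius,
            eyelid_coverage = eyelid_coverage,
            eyelid_intensity = eyelid_intensity,
            noise_sigma = noise_sigma,
            seed = as.integer(seed))
  class(p) <- "eye_scene_params"
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  if (any(p$pupil_axes <= 0)) stop("degenerate pupil axes")
  if (!(p$pupil_intensity < p$iris_intensity &&
        p$iris_intensity < p$sclera_intensity &&
        p$sclera_intensity < p$glint_intensity)) {
    stop("intensity ordering pupil < iris < sclera < glint violated")
  }
  if (p$eyelid_coverage < 0 || p$eyelid_coverage >= 1) {
    stop("eyelid_coverage must lie in [0, 1)")
  }
  w <- p$image_size[1]; h <- p$image_size[2]
  ext <- ellipse_extent(p$pupil_axes[1], p$pupil_axes[2], p$pupil_angle)
  lo <- p$pupil_center - ext
  hi <- p$pupil_center + ext
  if (lo[1] < 0 || lo[2] < 0 || hi[1] > w - 1 || hi[2] > h - 1) {
    stop("pupil out of frame")
  }
  invisible(p)
}

# Axis-aligned half-extents (x, y) of a rotated ellipse.
ellipse_extent <- function(a, b, angle_deg) {
  t <- angle_deg * pi / 180
  c(sqrt((a * cos(t))^2 + (b * sin(t))^2),
    sqrt((a * sin(t))^2 + (b * cos(t))^2))
}

# Eyelid clip line (y below which the eye is visible). -Inf when open.
eyelid_clip_y <- function(p) {
  if (p$eyelid_coverage <= 0) return(-Inf)
  ey <- ellipse_extent(p$pupil_axes[1], p$pupil_axes[2], p$pupil_angle)[2]
  (p$pupil_center[2] - ey) + p$eyelid_coverage * 2 * ey
}

#' Render one synthetic eye frame
#'
#' Composites sclera, iris disc, pupil ellipse, glints and eyelid with 4x4
#' supersampling, then adds sensor noise and quantizes to 8 bits. Ground truth
#' (recorded before noise) contains the true pupil ellipse, visible glint
#' centers and the pupil-corneal-reflection (PCR) vector to the first visible
#' glint.
#'
#' @param params an [eye_scene_params()] object.
#' @return list with `image` (numeric matrix, `dim = c(height, width)`,
#'   integer gray levels 0-255) and `truth` (list of scene ground truth).
#' @export
render_eye_frame <- function(params) {
  p <- validate_scene_params(params)
  w <- p$image_size[1]; h <- p$image_size[2]
  img <- matrix(p$sclera_intensity, nrow = h, ncol = w)
  clip_y <- eyelid_clip_y(p)
  cx <- p$pupil_center[1]; cy <- p$pupil_center[2]
  gl_abs <- lapply(p$glint_offsets, function(o) p$pupil_center + o)

  # Iris disc, painted at pixel resolution (nothing downstream localizes the
  # iris boundary, so it needs no supersampling).
  ix <- max(0, floor(cx - p$iris_radius)):min(w - 1, ceiling(cx + p$iris_radius))
  iy <- max(0, floor(cy - p$iris_radius)):min(h - 1, ceiling(cy + p$iris_radius))
  IX <- matrix(ix, nrow = length(iy), ncol = length(ix), byrow = TRUE)
  IY <- matrix(iy, nrow = length(iy), ncol = length(ix))
  disc <- (IX - cx)^2 + (IY - cy)^2 <= p$iris_radius^2
  sub <- img[iy + 1, ix + 1]
  sub[disc] <- p$iris_intensity
  img[iy + 1, ix + 1] <- sub

  # Region needing supersampled compositing: pupil ellipse plus glint discs
  # (the structures whose boundaries are localized at sub-pixel precision).
  ext <- ellipse_extent(p$pupil_axes[1], p$pupil_axes[2], p$pupil_angle)
  xs_lo <- floor(min(c(cx - ext[1],
                       vapply(gl_abs, `[`, 0, 1) - p$glint_radius)) - 2)
  xs_hi <- ceiling(max(c(cx + ext[1],
                         vapply(gl_abs, `[`, 0, 1) + p$glint_radius)) + 2)
  ys_lo <- floor(min(c(cy - ext[2],
                       vapply(gl_abs, `[`, 0, 2) - p$glint_radius)) - 2)
  ys_hi <- ceiling(max(c(cy + ext[2],
                         vapply(gl_abs, `[`, 0, 2) + p$glint_radius)) + 2)
  xs_lo <- max(xs_lo, 0); ys_lo <- max(ys_lo, 0)
  xs_hi <- min(xs_hi, w - 1); ys_hi <- min(ys_hi, h - 1)

  px <- xs_lo:xs_hi; py <- ys_lo:ys_hi
  ss <- 4L
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  subx <- rep(px, each = ss) + rep(off, times = length(px))
  suby <- rep(py, each = ss) + rep(off, times = length(py))
  nX <- length(subx); nY <- length(suby)

  X <- matrix(subx, nrow = nY, ncol = nX, byrow = TRUE)
  Y <- matrix(suby, nrow = nY, ncol = nX)

  val <- matrix(p$sclera_intensity, nrow = nY, ncol = nX)
  in_iris <- (X - cx)^2 + (Y - cy)^2 <= p$iris_radius^2
  val[in_iris] <- p$iris_intensity

  t <- p$pupil_angle * pi / 180
  u <- X - cx; v <- Y - cy
  xr <- u * cos(t) + v * sin(t)
  yr <- -u * sin(t) + v * cos(t)
  in_pupil <- (xr / p$pupil_axes[1])^2 + (yr / p$pupil_axes[2])^2 <= 1
  val[in_pupil] <- p$pupil_intensity

  glint_truth <- list()
  for (g in gl_abs) {
    if (g[2] < clip_y) next  # glint hidden by the lid
    in_glint <- (X - g[1])^2 + (Y - g[2])^2 <= p$glint_radius^2
    val[in_glint] <- p$glint_intensity
    glint_truth[[length(glint_truth) + 1]] <- g
  }
  if (is.finite(clip_y)) val[Y < clip_y] <- p$eyelid_intensity

  # Average 4x4 subsample blocks back to pixel resolution.
  a <- array(val, dim = c(ss, length(py), ss, length(px)))
  s1 <- colSums(a)                       # (length(py), ss, length(px))
  s2 <- colSums(aperm(s1, c(2, 1, 3)))   # (length(py), length(px))
  img[py + 1, px + 1] <- s2 / (ss * ss)

  # Eyelid outside the composited region (full image width), with the same
  # per-row supersampled blending.
  if (is.finite(clip_y)) {
    rows <- 0:(h - 1)
    frac <- colMeans(outer(off, rows, `+`) < clip_y)
    aff <- which(frac > 0)
    cols <- setdiff(seq_len(w), px + 1)
    if (length(aff) && length(cols)) {
      blk <- img[aff, cols, drop = FALSE]
      img[aff, cols] <- frac[aff] * p$eyelid_intensity + (1 - frac[aff]) * blk
    }
  }

  truth <- list(
    pupil_center = p$pupil_center,
    pupil_axes = p$pupil_axes,
    pupil_angle = p$pupil_angle,
    glints = glint_truth,
    clip_y = clip_y,
    pcr = if (length(glint_truth)) p$pupil_center - glint_truth[[1]]
          else c(NA_real_, NA_real_)
  )

  if (p$noise_sigma > 0) {
    noise <- with_seed(p$seed,
                       matrix(stats::rnorm(h * w, 0, p$noise_sigma), h, w))
    img <- img + noise
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, truth = truth)
}

#' Nine-point calibration grid
#'
#' A 3x3 grid of screen calibration points numbered 1-9 row-major (1 top-left,
#' 5 center, 9 bottom-right). Points are placed at fractions `margin` and
#' `1 - margin` of the screen dimensions and clipped to valid pixel
#' coordinates `[0, size - 1]`, so `margin = 0` yields the exact screen
#' corners.
#'
#' @param screen_size numeric (width, height) in pixels.
#' @param margin fractional margin in [0, 0.5).
#' @return data.frame with columns `point`, `sx`, `sy`.
#' @export
make_calibration_grid <- function(screen_size, margin = 0.1) {
  w <- screen_size[1]; h <- screen_size[2]
  if (w <= 0 || h <= 0) stop("screen dimensions must be positive")
  if (margin < 0 || margin >= 0.5) stop("margin must lie in [0, 0.5)")
  fx <- margin * w + (0:2) * (1 - 2 * margin) * w / 2
  fy <- margin * h + (0:2) * (1 - 2 * margin) * h / 2
  fx <- pmin(fx, w - 1); fy <- pmin(fy, h - 1)
  data.frame(point = 1:9,
             sx = rep(fx, times = 3),
             sy = rep(fy, each = 3))
}

#' Ground-truth screen-to-PCR map used by the generator
#'
#' The generator places the pupil so that the frame's true PCR vector is a
#' known second-order polynomial of the (normalized) screen point of regard.
#' The downstream calibration then has to learn the forward PCR-to-screen
#' relation from rendered data. Coefficients are fixed package-wide so all
#' simulations share one plausible geometry: a linear gain of about 50 screen
#' pixels per PCR pixel (small pupil displacements are strongly amplified on
#' screen) plus mild quadratic distortion.
#'
#' @param screen_size numeric (width, height) in pixels.
#' @return object of class `gaze_inverse_map`.
#' @export
default_inverse_map <- function(screen_size = c(1280, 720)) {
  m <- list(screen_size = as.numeric(screen_size),
            coeffs_x = c(10, 24, 0, 0.8, 1.2, -0.6),
            coeffs_y = c(12, 0, 20, -0.7, 0.5, 1.0))
  class(m) <- "gaze_inverse_map"
  m
}

#' Evaluate the generator's screen-to-PCR map
#'
#' @param imap a [default_inverse_map()] object.
#' @param sx,sy screen coordinates (vectors), pixels.
#' @return matrix with columns `vx`, `vy` (PCR vector, pixels).
#' @export
pcr_from_por <- function(imap, sx, sy) {
  nx <- sx / imap$screen_size[1] - 0.5
  ny <- sy / imap$screen_size[2] - 0.5
  B <- cbind(1, nx, ny, nx * ny, nx^2, ny^2)
  cbind(vx = as.numeric(B %*% imap$coeffs_x),
        vy = as.numeric(B %*% imap$coeffs_y))
}

#' Fixation trajectory over a set of screen points
#'
#' @param points data.frame with columns `point`, `sx`, `sy` (for instance
#'   from [make_calibration_grid()]).
#' @param frames_per_point number of frames dwelling on each point.
#' @param screen_size numeric (width, height), pixels.
#' @return data.frame with columns `frame`, `sx`, `sy`, `phase`, `point`,
#'   `period`; `phase` is `"fixation"` throughout.
#' @export
make_fixation_trajectory <- function(points, frames_per_point,
                                     screen_size = c(1280, 720)) {
  n <- nrow(points)
  traj <- data.frame(
    frame = seq_len(n * frames_per_point) - 1L,
    sx = rep(points$sx, each = frames_per_point),
    sy = rep(points$sy, each = frames_per_point),
    phase = "fixation",
    point = rep(points$point, each = frames_per_point),
    period = rep(seq_len(n), each = frames_per_point))
  attr(traj, "screen_size") <- screen_size
  traj
}

#' Pursuit polyline trajectory with dwells at turning points
#'
#' The target dwells at the first turning point, moves at constant velocity to
#' the next, dwells there, and so on; periods are numbered consecutively
#' (dwell, move, dwell, ...), mirroring a standard smooth-pursuit protocol.
#' The number of motion frames per segment is either given directly or derived
#' from component speeds (pixels per second) and the frame rate: the segment
#' duration is the larger of |dx|/speed_x and |dy|/speed_y.
#'
#' @param turning_points data.frame with columns `point`, `sx`, `sy`, in visit
#'   order (points may repeat).
#' @param dwell_frames frames spent stationary at each turning point.
#' @param motion_frames frames per moving segment (scalar or one per segment);
#'   overrides `speed`/`fps` when given.
#' @param speed numeric (horizontal, vertical) target speed, px/s.
#' @param fps camera frame rate, frames per second.
#' @param screen_size numeric (width, height), pixels.
#' @return data.frame with columns `frame`, `sx`, `sy`, `phase`
#'   (`"fixation"` or `"pursuit"`), `point` (NA while moving), `period`.
#' @export
make_pursuit_trajectory <- function(turning_points, dwell_frames,
                                    motion_frames = NULL,
                                    speed = c(20, 10), fps = 30,
                                    screen_size = c(1280, 720)) {
  if (nrow(turning_points) < 1) stop("trajectory empty")
  n_seg <- nrow(turning_points) - 1
  if (is.null(motion_frames)) {
    motion_frames <- vapply(seq_len(n_seg), function(i) {
      d <- abs(c(turning_points$sx[i + 1] - turning_points$sx[i],
                 turning_points$sy[i + 1] - turning_points$sy[i]))
      # interior samples of the segment: its duration (the larger of the
      # per-axis travel times) times the frame rate, minus the endpoint
      # frames contributed by the dwells
      max(1L, ceiling(max(d / speed) * fps) - 1L)
    }, 0)
  } else if (length(motion_frames) == 1) {
    motion_frames <- rep(motion_frames, n_seg)
  }
  rows <- list()
  period <- 0L
  for (i in seq_len(nrow(turning_points))) {
    period <- period + 1L
    rows[[length(rows) + 1]] <- data.frame(
      sx = rep(turning_points$sx[i], dwell_frames),
      sy = rep(turning_points$sy[i], dwell_frames),
      phase = "fixation", point = turning_points$point[i], period = period)
    if (i <= n_seg) {
      period <- period + 1L
      N <- motion_frames[i]
      f <- seq_len(N) / (N + 1)
      rows[[length(rows) + 1]] <- data.frame(
        sx = turning_points$sx[i] + f * (turning_points$sx[i + 1] - turning_points$sx[i]),
        sy = turning_points$sy[i] + f * (turning_points$sy[i + 1] - turning_points$sy[i]),
        phase = "pursuit", point = NA_integer_, period = period)
    }
  }
  traj <- do.call(rbind, rows)
  traj <- cbind(frame = seq_len(nrow(traj)) - 1L, traj)
  attr(traj, "screen_size") <- screen_size
  traj
}

#' Standard pursuit visit order over the nine calibration points
#'
#' Visit order P1, P2, P6, P8, P4, P2, P3, P9, P7, P1: ten dwells joined by
#' nine moving segments (19 periods in total).
#'
#' @param grid data.frame from [make_calibration_grid()].
#' @return data.frame of turning points in visit order.
#' @export
pursuit_point_order <- function(grid) {
  grid[match(c(1, 2, 6, 8, 4, 2, 3, 9, 7, 1), grid$point), ]
}

#' Render an eye-image sequence following a gaze trajectory
#'
#' For each trajectory frame the true PCR vector is obtained from the
#' generator's screen-to-PCR map (plus optional fixation jitter and a constant
#' PCR offset emulating headset slippage after calibration); the glint is held
#' at a fixed image position and the pupil is placed at glint + PCR, so the
#' rendered frame's PCR vector matches the trajectory by construction.
#'
#' @param trajectory data.frame from [make_fixation_trajectory()] or
#'   [make_pursuit_trajectory()].
#' @param inverse_map a [default_inverse_map()] object.
#' @param scene an [eye_scene_params()] object supplying photometry, axes and
#'   noise level; its pupil center is reinterpreted as the fixed glint
#'   position plus the nominal glint offset.
#' @param jitter_sd per-frame Gaussian jitter of the pupil center (pixels),
#'   emulating fixation instability.
#' @param pcr_offset constant (dx, dy) added to every true PCR vector,
#'   emulating camera/headset slippage relative to the calibration session.
#' @return list with `frames` (list of image matrices) and `truth`
#'   (data.frame: frame, px, py, a, b, angle, gx, gy, vx, vy, sx, sy, phase,
#'   point, period).
#' @export
render_sequence <- function(trajectory, inverse_map, scene,
                            jitter_sd = 0, pcr_offset = c(0, 0)) {
  if (is.null(trajectory) || nrow(trajectory) == 0) stop("trajectory empty")
  n <- nrow(trajectory)
  glint_pos <- scene$pupil_center + scene$glint_offsets[[1]]
  pcr <- pcr_from_por(inverse_map, trajectory$sx, trajectory$sy)
  pcr[, 1] <- pcr[, 1] + pcr_offset[1]
  pcr[, 2] <- pcr[, 2] + pcr_offset[2]
  seeds <- with_seed(scene$seed, sample.int(.Machine$integer.max - 1, n))
  jit <- if (jitter_sd > 0) {
    with_seed(scene$seed + 1L, matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2))
  } else matrix(0, n, 2)

  frames <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    v <- pcr[i, ] + jit[i, ]
    pc <- glint_pos + v
    p_i <- scene
    p_i$pupil_center <- pc
    p_i$glint_offsets <- list(glint_pos - pc)
    p_i$seed <- seeds[i]
    r <- render_eye_frame(p_i)
    frames[[i]] <- r$image
    truth[[i]] <- data.frame(
      frame = trajectory$frame[i],
      px = pc[1], py = pc[2],
      a = scene$pupil_axes[1], b = scene$pupil_axes[2],
      angle = scene$pupil_angle,
      gx = glint_pos[1], gy = glint_pos[2],
      vx = v[1], vy = v[2],
      sx = trajectory$sx[i], sy = trajectory$sy[i],
      phase = trajectory$phase[i],
      point = trajectory$point[i],
      period = trajectory$period[i])
  }
  list(frames = frames, truth = do.call(rbind, truth))
}

#' Parameter-level (image-free) observation stream for a trajectory
#'
#' Generates the PCR observation stream a perfect feature extractor would
#' produce, without rendering images: true PCR from the generator map, plus
#' slippage offset and i.i.d. Gaussian measurement noise. Used for fast
#' filter-level experiments where pixel-level effects are not under study.
#'
#' @inheritParams render_sequence
#' @param noise_sd i.i.d. Gaussian noise added to each observed PCR
#'   component, pixels.
#' @param seed integer RNG seed.
#' @return data.frame: frame, vx, vy (observed), true_vx, true_vy, sx, sy,
#'   phase, point, period, missing (all FALSE).
#' @export
simulate_pcr_stream <- function(trajectory, inverse_map,
                                noise_sd = 0, pcr_offset = c(0, 0),
                                seed = 1L) {
  if (is.null(trajectory) || nrow(trajectory) == 0) stop("trajectory empty")
  n <- nrow(trajectory)
  pcr <- pcr_from_por(inverse_map, trajectory$sx, trajectory$sy)
  tv <- sweep(pcr, 2, pcr_offset, `+`)
  noise <- if (noise_sd > 0) {
    with_seed(seed, matrix(stats::rnorm(2 * n, 0, noise_sd), n, 2))
  } else matrix(0, n, 2)
  data.frame(frame = trajectory$frame,
             vx = tv[, 1] + noise[, 1],
             vy = tv[, 2] + noise[, 2],
             true_vx = tv[, 1], true_vy = tv[, 2],
             sx = trajectory$sx, sy = trajectory$sy,
             phase = trajectory$phase,
             point = trajectory$point,
             period = trajectory$period,
             missing = FALSE)
}
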