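# Pupil / glint parameter extraction from the tracked pupil crop.
#
# The pupil is segmented with a low threshold and morphological filtering
# (closing fills the glint hole, opening removes hairline artifacts). Edge
# points for the ellipse fit are selected with the star-ray method restricted
# to the left and right pupil flanks -- angle windows [-70, 60] and
# [120, 250] degrees -- so that upper/lower eyelid edges never enter the fit,
# which keeps the pupil center stable under partial occlusion. The glint
# (Purkinje image) center is the intensity-weighted centroid of the bright
# blob nearest the pupil; pupil center minus glint center is the
# pupil-corneal-reflection (PCR) vector handed to the gaze map.
#
# Angle convention: 0 degrees along +x (image right), angles increase toward
# +y (downward in display orientation). The two windows therefore cover the
# right flank (-70..60) and the left flank (120..250) of the pupil.

#' Feature-extraction configuration
#'
#' @param threshold_offset gray levels added to the 5th-percentile intensity
#'   of the crop to form the low pupil threshold.
#' @param use_otsu use Otsu's threshold instead of the quantile rule.
#' @param close_radius,open_radius radii (px) of the elliptical structuring
#'   elements for morphological closing (fills glint holes) and opening.
#' @param ray_step angular spacing of star rays, degrees.
#' @param ray_windows list of closed angle intervals (degrees) within which
#'   rays are cast.
#' @param march_step radial sampling step along each ray, pixels.
#' @param glint_threshold_frac glint threshold as a fraction of the crop
#'   maximum intensity.
#' @param glint_min_level absolute gray-level floor for glint segmentation:
#'   when no pixel reaches it the glint is reported missing (a blink frame)
#'   rather than latching onto skin or sclera.
#' @param occlusion_area_frac pupil-mask area below this fraction of the
#'   rolling median area flags the frame as occluded.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(threshold_offset = 25, use_otsu = FALSE,
                           close_radius = 5, open_radius = 2,
                           ray_step = 2,
                           ray_windows = list(c(-70, 60), c(120, 250)),
                           march_step = 0.5,
                           glint_threshold_frac = 0.9,
                           glint_min_level = 200,
                           occlusion_area_frac = 0.6) {
  structure(list(threshold_offset = threshold_offset, use_otsu = use_otsu,
                 close_radius = close_radius, open_radius = open_radius,
                 ray_step = ray_step, ray_windows = ray_windows,
                 march_step = march_step,
                 glint_threshold_frac = glint_threshold_frac,
                 glint_min_level = glint_min_level,
                 occlusion_area_frac = occlusion_area_frac),
            class = "feature_config")
}

# Low pupil threshold for a crop: 5th percentile (the pupil is the darkest
# sizable structure in the crop) plus an offset, or Otsu's method.
pupil_threshold <- function(img, config) {
  if (isTRUE(config$use_otsu)) {
    return(EBImage::otsu(EBImage::Image(t(img) / 255)) * 255)
  }
  as.numeric(stats::quantile(img, 0.05)) + config$threshold_offset
}

odd_brush <- function(radius) EBImage::makeBrush(2 * radius + 1, shape = "disc")

#' Segment the pupil blob in a crop
#'
#' Low-threshold binarization, morphological closing then opening, and
#' retention of the largest connected component.
#'
#' @param img grayscale pupil-crop matrix.
#' @param config a [feature_config()].
#' @param threshold optional absolute threshold override.
#' @return logical matrix pupil mask, with attribute `threshold`.
#' @export
segment_pupil <- function(img, config = feature_config(), threshold = NULL) {
  thr <- threshold %||% pupil_threshold(img, config)
  mask <- (img < thr) * 1
  # a pupil is a dark structure against a brighter surround; a mask covering
  # (almost) the whole crop means there is no such structure
  if (!any(mask > 0) || mean(mask) > 0.9) stop("no pupil pixels")
  if (config$close_radius > 0) {
    mask <- EBImage::closing(mask, odd_brush(config$close_radius))
  }
  if (config$open_radius > 0) {
    mask <- EBImage::opening(mask, odd_brush(config$open_radius))
  }
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  if (length(tab) == 0) stop("no pupil pixels")
  keep <- which.max(tab)
  out <- lab == keep
  attr(out, "threshold") <- thr
  out
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)  # (x, y), 0-based
}

# Detect an eyelid occlusion line: when the eyelid clips the pupil, the top
# boundary of the pupil mask degenerates into a long horizontal run. Returns
# the 0-based row of that run, or -Inf when the top boundary looks like a
# smooth ellipse apex. `min_frac` is the minimal run length as a fraction of
# the mask width.
occlusion_clip_row <- function(mask, min_frac = 0.4) {
  cols <- which(colSums(mask) > 0)
  if (length(cols) < 4) return(-Inf)
  top <- vapply(cols, function(j) which(mask[, j])[1], 0L)
  tab <- table(top)
  mode_count <- max(tab)
  if (mode_count >= min_frac * length(cols)) {
    as.integer(names(tab)[which.max(tab)]) - 1L
  } else {
    -Inf
  }
}

#' Star-ray edge-point selection on the pupil flanks
#'
#' Casts rays from a seed point (default: pupil-mask centroid) at a fixed
#' angular step, restricted to the configured left/right angle windows
#' (closed intervals). Each ray marches outward in sub-pixel steps and
#' returns the first dark-to-bright threshold crossing, localized by linear
#' interpolation of the two straddling intensity samples. Crossings caused by
#' bright spots interior to the pupil blob (the glint) are rejected: a
#' genuine boundary crossing must leave the morphologically closed pupil
#' mask.
#'
#' @param img grayscale pupil-crop matrix.
#' @param mask logical pupil mask from [segment_pupil()] (computed when
#'   `NULL`).
#' @param seed_point (x, y) ray origin; defaults to the mask centroid.
#' @param config a [feature_config()].
#' @param threshold absolute edge threshold; defaults to the segmentation
#'   threshold.
#' @return matrix with columns `x`, `y` of sub-pixel edge points (>= 6 rows,
#'   otherwise an error).
#' @export
star_ray_edges <- function(img, mask = NULL, seed_point = NULL,
                           config = feature_config(), threshold = NULL) {
  if (is.null(mask)) mask <- segment_pupil(img, config, threshold)
  thr <- threshold %||% attr(mask, "threshold") %||%
    pupil_threshold(img, config)
  if (is.null(seed_point)) seed_point <- mask_centroid(mask)
  clip_row <- occlusion_clip_row(mask)
  angles <- unlist(lapply(config$ray_windows, function(wd) {
    seq(wd[1], wd[2], by = config$ray_step)
  }))
  t_max <- max(dim(img))
  ts <- seq(config$march_step, t_max, by = config$march_step)
  pts <- list()
  for (ang in angles) {
    th <- ang * pi / 180
    xs <- seed_point[1] + ts * cos(th)
    ys <- seed_point[2] + ts * sin(th)
    inside <- xs >= 0 & xs <= ncol(img) - 1 & ys >= 0 & ys <= nrow(img) - 1
    if (sum(inside) < 2) next
    xs <- xs[inside]; ys <- ys[inside]; tt <- ts[inside]
    iv <- bilinear_sample(img, xs, ys)
    cross <- which(iv[-1] >= thr & iv[-length(iv)] < thr)
    for (ci in cross) {
      f <- (thr - iv[ci]) / (iv[ci + 1] - iv[ci])
      tc <- tt[ci] + f * (tt[ci + 1] - tt[ci])
      ex <- seed_point[1] + tc * cos(th)
      ey <- seed_point[2] + tc * sin(th)
      # reject interior bright spots: just beyond a true pupil boundary the
      # closed mask must be FALSE along a short look-ahead stretch
      look <- c(0.75, 1.5, 2.25, 3)
      bx <- round(seed_point[1] + (tc + look) * cos(th))
      by <- round(seed_point[2] + (tc + look) * sin(th))
      ok <- bx >= 0 & bx <= ncol(img) - 1 & by >= 0 & by <= nrow(img) - 1
      interior <- any(mask[cbind(by[ok] + 1, bx[ok] + 1)])
      # reject crossings on a detected eyelid occlusion line: those edges
      # belong to the lid, not the pupil boundary
      on_lid <- is.finite(clip_row) && ey <= clip_row + 1.5
      if (!interior && !on_lid) {
        pts[[length(pts) + 1]] <- c(ex, ey)
        break
      }
      if (on_lid) break  # the ray has left the pupil through the lid
    }
  }
  if (length(pts) < 6) stop("insufficient edge support")
  out <- do.call(rbind, pts)
  colnames(out) <- c("x", "y")
  out
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse (numerically stable
#' Halir-Flusser formulation of the direct least-squares method) and converts
#' it to geometric parameters. Exact on noiseless samples from an ellipse.
#' For a perfect circle the orientation is undefined and the angle is
#' returned as 0 with `a = b`.
#'
#' @param points matrix or data.frame with columns x, y (>= 6 points).
#' @return list of class `pupil_ellipse`: `center` (x, y), `axes`
#'   (semi-major a >= semi-minor b), `angle` (degrees in (-90, 90],
#'   orientation of the major axis).
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 6) stop("at least 6 points are required")
  x <- pts[, 1]; y <- pts[, 2]
  # center/scale for conditioning
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y), 1e-12)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point configuration"))
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("no ellipse fits the points")
  a1 <- vecs[, ok[1]]
  coef_s <- c(a1, as.numeric(T1 %*% a1))
  # undo normalization: conic in original coordinates
  A <- coef_s[1] / sc^2
  B <- coef_s[2] / sc^2
  C <- coef_s[3] / sc^2
  D <- coef_s[4] / sc - 2 * A * mx - B * my
  E <- coef_s[5] / sc - 2 * C * my - B * mx
  Fc <- coef_s[6] + A * mx^2 + B * mx * my + C * my^2 -
    coef_s[4] * mx / sc - coef_s[5] * my / sc
  conic_to_ellipse(c(A, B, C, D, E, Fc))
}

# Convert conic coefficients (A, B, C, D, E, F) of
# A x^2 + B xy + C y^2 + D x + E y + F = 0 to geometric parameters.
conic_to_ellipse <- function(k) {
  if (k[1] < 0) k <- -k  # normalize sign so the quadratic form is pos. def.
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("conic is not an ellipse")
  xc <- (2 * C * D - B * E) / den
  yc <- (2 * A * E - B * D) / den
  mu <- A * xc^2 + B * xc * yc + C * yc^2 + D * xc + E * yc + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  semis <- sqrt(-mu / eg$values)      # eigenvalues descending: minor first
  if (any(!is.finite(semis)) || any(semis <= 0)) {
    stop("conic is not an ellipse")
  }
  b <- semis[1]; a <- semis[2]        # larger semi-axis from smaller eigenvalue
  if (abs(a - b) < 1e-9 * max(a, b)) {
    angle <- 0
    a <- b <- (a + b) / 2
  } else {
    vmaj <- eg$vectors[, 2]           # eigenvector of the smaller eigenvalue
    angle <- atan2(vmaj[2], vmaj[1]) * 180 / pi
    if (angle <= -90) angle <- angle + 180
    if (angle > 90) angle <- angle - 180
  }
  structure(list(center = c(xc, yc), axes = c(a, b), angle = angle),
            class = "pupil_ellipse")
}

#' Sample points on an ellipse (utility, e.g. for tests and figures)
#'
#' @param center (x, y); `axes` (a, b); `angle` degrees; `n` points.
#' @param center,axes,angle,n ellipse parameters and number of points.
#' @return matrix with columns x, y.
#' @export
ellipse_points <- function(center, axes, angle, n = 40) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- angle * pi / 180
  x <- center[1] + axes[1] * cos(t) * cos(th) - axes[2] * sin(t) * sin(th)
  y <- center[2] + axes[1] * cos(t) * sin(th) + axes[2] * sin(t) * cos(th)
  cbind(x = x, y = y)
}

#' Glint (Purkinje image) center by thresholded centroiding
#'
#' Segments bright pixels above `glint_threshold_frac * max(img)`, labels
#' blobs, and returns the intensity-weighted centroid of the blob nearest the
#' pupil center.
#'
#' @param img grayscale pupil-crop matrix.
#' @param pupil_center (x, y) reference for nearest-blob selection; defaults
#'   to the crop center.
#' @param config a [feature_config()].
#' @param composite if `TRUE`, returns the joint centroid of all bright blobs
#'   instead of the nearest one (multi-glint option).
#' @return list: `center` (x, y sub-pixel, or `c(NA, NA)`), `missing`
#'   (logical).
#' @export
glint_center <- function(img, pupil_center = NULL, config = feature_config(),
                         composite = FALSE) {
  mx <- max(img)
  if (mx < config$glint_min_level) {
    return(list(center = c(NA_real_, NA_real_), missing = TRUE))
  }
  thr <- config$glint_threshold_frac * mx
  mask <- img >= thr
  if (!any(mask)) {
    return(list(center = c(NA_real_, NA_real_), missing = TRUE))
  }
  if (is.null(pupil_center)) {
    pupil_center <- c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2)
  }
  lab <- EBImage::bwlabel(mask * 1)
  ids <- if (composite) 0 else seq_len(max(lab))
  wcent <- function(sel) {
    idx <- which(sel, arr.ind = TRUE)
    wts <- img[sel]
    c(sum((idx[, 2] - 1) * wts), sum((idx[, 1] - 1) * wts)) / sum(wts)
  }
  if (composite) {
    return(list(center = wcent(lab > 0), missing = FALSE))
  }
  cents <- lapply(ids, function(i) wcent(lab == i))
  d <- vapply(cents, function(cc) vnorm(cc - pupil_center), 0)
  list(center = cents[[which.min(d)]], missing = FALSE)
}

#' Pupil-corneal-reflection vector
#'
#' Pupil center minus glint center, in pixels. Invariant to joint image
#' translation.
#'
#' @param ellipse a `pupil_ellipse` (or any list with a `center` field).
#' @param glint (x, y) glint center.
#' @return numeric (vx, vy).
#' @export
pcr_vector <- function(ellipse, glint) {
  ctr <- if (is.list(ellipse)) ellipse$center else ellipse
  as.numeric(ctr - glint)
}

#' Extract a full pupil observation from a crop
#'
#' Runs segmentation, star-ray edge selection, ellipse fitting and glint
#' centroiding on one pupil crop. Coordinates are reported in the frame of
#' the crop plus `offset` (pass the crop's top-left corner to obtain
#' full-image coordinates).
#'
#' @param img grayscale pupil-crop matrix.
#' @param config a [feature_config()].
#' @param offset (x, y) added to all reported coordinates.
#' @param ref_area reference pupil-mask area (px) for the occlusion flag
#'   (e.g. a rolling median over recent frames); `NULL` disables the flag.
#' @return one-row data.frame: `px, py, a, b, angle, gx, gy, vx, vy,
#'   mask_area, occluded, glint_missing, valid`.
#' @export
extract_observation <- function(img, config = feature_config(),
                                offset = c(0, 0), ref_area = NULL) {
  na_row <- data.frame(px = NA_real_, py = NA_real_, a = NA_real_,
                       b = NA_real_, angle = NA_real_, gx = NA_real_,
                       gy = NA_real_, vx = NA_real_, vy = NA_real_,
                       mask_area = NA_real_, occluded = FALSE,
                       glint_missing = TRUE, valid = FALSE)
  mask <- tryCatch(segment_pupil(img, config), error = function(e) NULL)
  if (is.null(mask)) return(na_row)
  area <- sum(mask)
  occluded <- !is.null(ref_area) && area < config$occlusion_area_frac * ref_area
  ell <- tryCatch({
    pts <- star_ray_edges(img, mask, config = config)
    fit_ellipse(pts)
  }, error = function(e) NULL)
  if (is.null(ell)) {
    na_row$mask_area <- area
    na_row$occluded <- occluded
    return(na_row)
  }
  gl <- glint_center(img, pupil_center = ell$center, config = config)
  v <- if (gl$missing) c(NA_real_, NA_real_) else pcr_vector(ell, gl$center)
  data.frame(px = ell$center[1] + offset[1], py = ell$center[2] + offset[2],
             a = ell$axes[1], b = ell$axes[2], angle = ell$angle,
             gx = gl$center[1] + offset[1], gy = gl$center[2] + offset[2],
             vx = v[1], vy = v[2], mask_area = area,
             occluded = occluded, glint_missing = gl$missing,
             valid = !gl$missing && !occluded)
}
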