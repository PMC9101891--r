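# End-to-end orchestration: calibrate -> track -> extract -> map -> filter,
# plus the evaluation metrics (per-point mean error and error variance for
# raw / CV-filtered / CA-filtered estimates, tracking precision curve,
# minimum covering circles of the POR clouds).

#' Run configuration for the evaluation tasks
#'
#' Collects every tunable of an end-to-end run. The defaults define the
#' package's reference simulation: a 1280x720 screen with a 9-point
#' calibration grid at 10% margin, the default eye scene with 2 gray levels
#' of sensor noise, sub-pixel fixation jitter, PCR observation noise of
#' 0.22 px per axis (about 12 screen px after mapping), and a constant
#' headset-slippage offset of (0.9, -0.7) px between the calibration and the
#' task session (about 55 screen px of systematic error after mapping).
#'
#' @param screen_size screen (width, height), px.
#' @param margin calibration-grid margin fraction.
#' @param scene an [eye_scene_params()] used for rendered runs.
#' @param fixation_jitter_sd per-frame pupil-center jitter (px, rendered
#'   runs).
#' @param pcr_noise_sd i.i.d. PCR observation noise (px, parameter-level
#'   runs).
#' @param slippage constant PCR offset (px) applied to task (not calibration)
#'   frames, emulating glasses slippage after calibration.
#' @param cal_frames_per_point,task_frames_per_point dwell lengths for the
#'   calibration and evaluation fixations.
#' @param dwell_frames,motion_frames dwell / per-segment motion lengths of
#'   the pursuit protocol.
#' @param tracker a [kcf_config()].
#' @param features a [feature_config()].
#' @param filter an [adaptive_config()].
#' @param kf_q process-noise scale for both kinematic models.
#' @param thresholds precision-curve thresholds, px.
#' @param min_valid_frames calibration/evaluation points with fewer valid
#'   frames are excluded with a warning.
#' @param seed master RNG seed; recorded in all outputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(screen_size = c(1280, 720), margin = 0.1,
                       scene = eye_scene_params(noise_sigma = 2),
                       fixation_jitter_sd = 0.1,
                       pcr_noise_sd = 0.22,
                       slippage = c(0.9, -0.7),
                       cal_frames_per_point = 10,
                       task_frames_per_point = 20,
                       dwell_frames = 50, motion_frames = 20,
                       tracker = kcf_config(),
                       features = feature_config(),
                       filter = adaptive_config(),
                       kf_q = 1e-3,
                       thresholds = 0:30,
                       min_valid_frames = 10,
                       seed = 1L) {
  structure(list(screen_size = screen_size, margin = margin, scene = scene,
                 fixation_jitter_sd = fixation_jitter_sd,
                 pcr_noise_sd = pcr_noise_sd, slippage = slippage,
                 cal_frames_per_point = cal_frames_per_point,
                 task_frames_per_point = task_frames_per_point,
                 dwell_frames = dwell_frames, motion_frames = motion_frames,
                 tracker = tracker, features = features, filter = filter,
                 kf_q = kf_q, thresholds = thresholds,
                 min_valid_frames = min_valid_frames,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Tracking precision curve
#'
#' For each threshold `t`, the fraction of frames whose tracked center lies
#' within `t` pixels of the true center. Non-decreasing in `t`, bounded by 1.
#'
#' @param tracked n x 2 matrix (x, y) of tracked centers.
#' @param truth n x 2 matrix of true centers (same length).
#' @param thresholds numeric thresholds, px.
#' @return data.frame: `threshold`, `precision`.
#' @export
precision_curve <- function(tracked, truth, thresholds = 0:30) {
  tracked <- as.matrix(tracked); truth <- as.matrix(truth)
  if (nrow(tracked) != nrow(truth)) stop("length mismatch")
  err <- sqrt(rowSums((tracked - truth)^2))
  data.frame(threshold = thresholds,
             precision = vapply(thresholds, function(t) mean(err <= t), 0))
}

# ---- minimum covering circle (Welzl-type incremental algorithm) ----

circle2 <- function(p, q) {
  c0 <- (p + q) / 2
  list(center = c0, radius = vnorm(p - q) / 2)
}

circle3 <- function(p, q, r) {
  ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = vnorm(p - ctr))
}

in_circle <- function(circ, p, tol = 1e-9) {
  !is.null(circ) && vnorm(p - circ$center) <= circ$radius + tol
}

#' Minimum covering circle of a 2-D point set
#'
#' Incremental (move-to-front) algorithm; expected linear time after a
#' deterministic seeded shuffle.
#'
#' @param points n x 2 matrix or data.frame.
#' @return list: `center` (x, y), `radius`.
#' @export
min_cover_circle <- function(points) {
  pts <- as.matrix(points)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n == 0) stop("no points")
  if (n == 1) return(list(center = pts[1, ], radius = 0))
  ord <- with_seed(42L, sample.int(n))
  pts <- pts[ord, , drop = FALSE]
  circ <- circle2(pts[1, ], pts[2, ])
  for (i in seq_len(n)) {
    if (in_circle(circ, pts[i, ])) next
    circ <- list(center = pts[i, ], radius = 0)
    for (j in seq_len(i - 1)) {
      if (in_circle(circ, pts[j, ])) next
      circ <- circle2(pts[i, ], pts[j, ])
      for (k in seq_len(j - 1)) {
        if (in_circle(circ, pts[k, ])) next
        c3 <- circle3(pts[i, ], pts[j, ], pts[k, ])
        if (!is.null(c3)) circ <- c3
      }
    }
  }
  circ
}

#' Extract observations from a tracked frame sequence
#'
#' Crops each frame to the tracked window and runs [extract_observation()];
#' also records the inter-frame motion energy of consecutive crops (used by
#' the adaptive filter) and an occlusion flag against the rolling median mask
#' area of the last 10 valid frames.
#'
#' @param frames list of grayscale frames.
#' @param track data.frame from [track_sequence()].
#' @param config a [feature_config()].
#' @return data.frame: one row per frame with global-coordinate observation
#'   columns plus `m` and `missing`.
#' @export
extract_sequence <- function(frames, track, config = feature_config()) {
  n <- length(frames)
  rows <- vector("list", n)
  areas <- numeric(0)
  prev_crop <- NULL
  for (i in seq_len(n)) {
    sz <- c(round(track$h[i]), round(track$w[i]))
    ctr <- c(track$cx[i], track$cy[i])
    crop <- get_subwindow(frames[[i]], ctr, sz)
    x0 <- round(ctr[1]) - floor(sz[2] / 2)
    y0 <- round(ctr[2]) - floor(sz[1] / 2)
    ref <- if (length(areas)) stats::median(areas) else NULL
    ob <- extract_observation(crop, config, offset = c(x0, y0),
                              ref_area = ref)
    ob$frame <- track$frame[i]
    ob$m <- if (!is.null(prev_crop) && all(dim(prev_crop) == dim(crop))) {
      eye_difference(crop / 255, prev_crop / 255)
    } else NA_real_
    ob$missing <- !ob$valid
    if (isTRUE(ob$valid)) {
      areas <- c(areas, ob$mask_area)
      if (length(areas) > 10) areas <- areas[-1]
    }
    prev_crop <- crop
    rows[[i]] <- ob
  }
  out <- do.call(rbind, rows)
  out[, c("frame", setdiff(names(out), "frame"))]
}

# Per-point error statistics for one estimated POR table.
point_stats <- function(est, truth, variant, min_valid = 10) {
  d <- data.frame(point = truth$point,
                  err = sqrt((est$sx - truth$sx)^2 + (est$sy - truth$sy)^2))
  d <- d[!is.na(d$err) & !is.na(d$point), ]
  sp <- split(d, d$point)
  res <- do.call(rbind, lapply(sp, function(g) {
    data.frame(variant = variant, point = g$point[1], n = nrow(g),
               mean_error = mean(g$err), variance = stats::var(g$err))
  }))
  drop <- res$n < min_valid
  if (any(drop)) {
    warning(sprintf("excluding point(s) %s with < %d valid frames",
                    paste(res$point[drop], collapse = ", "), min_valid))
    res <- res[!drop, ]
  }
  res
}

# Calibration from a parameter-level or extracted observation stream.
calibrate_from_obs <- function(obs, grid, screen_size) {
  agg <- aggregate_calibration(obs)
  agg <- agg[agg$point %in% grid$point, ]
  calibrate_mapping(agg[, c("vx", "vy")],
                    grid[match(agg$point, grid$point), c("sx", "sy")],
                    screen_size = screen_size)
}

# Speed-normalization constant from a calibration observation stream: the
# 95th percentile of within-fixation gaze-point speeds (inter-point
# transitions excluded, so saccade jumps do not inflate the scale).
calibration_v_scale <- function(obs) {
  dq <- cbind(diff(obs$vx), diff(obs$vy))
  same <- if (!is.null(obs$point)) {
    obs$point[-1] == obs$point[-nrow(obs)]
  } else rep(TRUE, nrow(obs) - 1)
  v <- sqrt(rowSums(dq^2))[same & !is.na(rowSums(dq))]
  max(as.numeric(stats::quantile(v, 0.95, na.rm = TRUE)), 1e-9)
}

# Produce raw / kal_cv / kal_ca POR tables from an observation stream.
# `split_by` (e.g. the calibration-point id) filters each group as its own
# sequence with a fresh filter state, mirroring per-point processing of the
# fixation task; NULL filters the stream as one continuous recording.
estimate_variants <- function(obs, model, config, split_by = NULL) {
  flt_cfg <- config$filter
  run_filter <- function(type) {
    km <- kf_model(type, q = config$kf_q)
    if (is.null(split_by)) {
      filter_sequence(obs, type, flt_cfg, model = km)
    } else {
      parts <- lapply(split(seq_len(nrow(obs)), split_by), function(ix) {
        cbind(ix = ix, filter_sequence(obs[ix, ], type, flt_cfg, model = km))
      })
      res <- do.call(rbind, parts)
      res[order(res$ix), -1]
    }
  }
  cv <- run_filter("cv")
  ca <- run_filter("ca")
  list(raw = map_por(model, obs[, c("vx", "vy")]),
       kal_cv = map_por(model, cv[, c("vx", "vy")]),
       kal_ca = map_por(model, ca[, c("vx", "vy")]),
       filtered = list(cv = cv, ca = ca))
}

#' Run the nine-point gaze (fixation) task
#'
#' Renders (or parameter-level simulates) a calibration session on the
#' 9-point grid, fits the polynomial map, then simulates the evaluation
#' session -- same grid, with observation noise and the configured slippage
#' offset -- and reports per-point and overall mean error and error variance
#' for the raw, CV-filtered and CA-filtered estimates, plus the minimum
#' covering circle of each POR cloud. In rendered mode the full image
#' pipeline runs (KCF tracking + feature extraction) and the tracking
#' precision curve is included.
#'
#' @param config a [run_config()].
#' @param render if `TRUE`, render eye images and run the full pipeline; if
#'   `FALSE`, run at observation level (a perfect extractor with i.i.d. PCR
#'   noise).
#' @return list of class `eval_report`.
#' @export
run_gaze_task <- function(config = run_config(), render = FALSE) {
  grid <- make_calibration_grid(config$screen_size, config$margin)
  imap <- default_inverse_map(config$screen_size)
  cal_traj <- make_fixation_trajectory(grid, config$cal_frames_per_point,
                                       config$screen_size)
  task_traj <- make_fixation_trajectory(grid, config$task_frames_per_point,
                                        config$screen_size)
  if (render) {
    scene_cal <- config$scene
    scene_cal$seed <- config$seed
    cal <- render_sequence(cal_traj, imap, scene_cal,
                           jitter_sd = config$fixation_jitter_sd)
    scene_task <- config$scene
    scene_task$seed <- config$seed + 1L
    task <- render_sequence(task_traj, imap, scene_task,
                            jitter_sd = config$fixation_jitter_sd,
                            pcr_offset = config$slippage)
    cal_track <- track_sequence(cal$frames, config$tracker)
    cal_obs <- extract_sequence(cal$frames, cal_track, config$features)
    cal_obs$point <- cal_traj$point
    task_track <- track_sequence(task$frames, config$tracker)
    task_obs <- extract_sequence(task$frames, task_track, config$features)
    task_obs$point <- task_traj$point
    prec <- precision_curve(task_track[, c("cx", "cy")],
                            task$truth[, c("px", "py")],
                            config$thresholds)
    truth <- task$truth
  } else {
    cal_obs <- simulate_pcr_stream(cal_traj, imap,
                                   noise_sd = config$pcr_noise_sd,
                                   seed = config$seed)
    cal_obs$valid <- TRUE
    task_obs <- simulate_pcr_stream(task_traj, imap,
                                    noise_sd = config$pcr_noise_sd,
                                    pcr_offset = config$slippage,
                                    seed = config$seed + 1L)
    task_obs$point <- task_traj$point
    prec <- NULL
    truth <- task_traj
  }
  model <- calibrate_from_obs(cal_obs, grid, config$screen_size)
  if (is.null(config$filter$v_scale)) {
    config$filter$v_scale <- calibration_v_scale(cal_obs)
  }
  est <- estimate_variants(task_obs, model, config,
                           split_by = task_obs$point)

  per_point <- rbind(point_stats(est$raw, truth, "raw", config$min_valid_frames),
                     point_stats(est$kal_cv, truth, "kal_cv", config$min_valid_frames),
                     point_stats(est$kal_ca, truth, "kal_ca", config$min_valid_frames))
  overall <- do.call(rbind, lapply(split(per_point, per_point$variant),
    function(g) data.frame(variant = g$variant[1],
                           mean_error = mean(g$mean_error),
                           variance = mean(g$variance))))
  rownames(overall) <- NULL
  circles <- lapply(list(raw = est$raw, kal_cv = est$kal_cv,
                         kal_ca = est$kal_ca), function(e) {
    lapply(split(seq_len(nrow(e)), truth$point), function(ix) {
      min_cover_circle(e[ix, c("sx", "sy")])
    })
  })
  structure(list(version = "1.0", task = "gaze", seed = config$seed,
                 rendered = render, model = model,
                 per_point = per_point, overall = overall,
                 precision = prec, circles = circles,
                 estimates = est, truth = truth,
                 observations = task_obs),
            class = "eval_report")
}

#' Run the smooth-pursuit (saccade) task
#'
#' The target traverses the standard polyline over the calibration grid
#' (P1-P2-P6-P8-P4-P2-P3-P9-P7-P1) with dwells at the turning points.
#' Calibration is performed exactly as in the gaze task; traces of the raw
#' and filtered PORs are returned per period together with the transient
#' amplitude (largest Euclidean deviation of the estimate from the dwell
#' target) at each post-motion dwell.
#'
#' @param config a [run_config()].
#' @param render as in [run_gaze_task()].
#' @param turning_points optional data.frame of turning points overriding
#'   the standard order.
#' @param noise_sd observation noise override for the task session
#'   (defaults to `config$pcr_noise_sd`); the transient analysis is usually
#'   run noise-free so the deterministic filter lag is isolated.
#' @return list of class `eval_report` with elements `traces` and
#'   `transients`.
#' @export
run_saccade_task <- function(config = run_config(), render = FALSE,
                             turning_points = NULL, noise_sd = NULL) {
  grid <- make_calibration_grid(config$screen_size, config$margin)
  imap <- default_inverse_map(config$screen_size)
  tp <- turning_points %||% pursuit_point_order(grid)
  traj <- make_pursuit_trajectory(tp, config$dwell_frames,
                                  motion_frames = config$motion_frames,
                                  screen_size = config$screen_size)
  cal_traj <- make_fixation_trajectory(grid, config$cal_frames_per_point,
                                       config$screen_size)
  noise_sd <- noise_sd %||% config$pcr_noise_sd
  if (render) {
    scene_cal <- config$scene; scene_cal$seed <- config$seed
    cal <- render_sequence(cal_traj, imap, scene_cal,
                           jitter_sd = config$fixation_jitter_sd)
    cal_track <- track_sequence(cal$frames, config$tracker)
    cal_obs <- extract_sequence(cal$frames, cal_track, config$features)
    cal_obs$point <- cal_traj$point
    scene_task <- config$scene; scene_task$seed <- config$seed + 1L
    task <- render_sequence(traj, imap, scene_task,
                            jitter_sd = config$fixation_jitter_sd,
                            pcr_offset = config$slippage)
    task_track <- track_sequence(task$frames, config$tracker)
    task_obs <- extract_sequence(task$frames, task_track, config$features)
  } else {
    cal_obs <- simulate_pcr_stream(cal_traj, imap,
                                   noise_sd = config$pcr_noise_sd,
                                   seed = config$seed)
    cal_obs$valid <- TRUE
    task_obs <- simulate_pcr_stream(traj, imap, noise_sd = noise_sd,
                                    pcr_offset = config$slippage,
                                    seed = config$seed + 1L)
  }
  model <- calibrate_from_obs(cal_obs, grid, config$screen_size)
  if (is.null(config$filter$v_scale)) {
    config$filter$v_scale <- calibration_v_scale(cal_obs)
  }
  est <- estimate_variants(task_obs, model, config)
  traces <- data.frame(frame = traj$frame, period = traj$period,
                       phase = traj$phase, point = traj$point,
                       true_sx = traj$sx, true_sy = traj$sy,
                       raw_sx = est$raw$sx, raw_sy = est$raw$sy,
                       cv_sx = est$kal_cv$sx, cv_sy = est$kal_cv$sy,
                       ca_sx = est$kal_ca$sx, ca_sy = est$kal_ca$sy)

  # Transient amplitude at each post-motion dwell: the largest Euclidean
  # deviation of a filtered trace from the raw trace during the dwell. The
  # raw estimate settles on the (bias-shifted) dwell value immediately, so
  # this isolates the filter's own lag/overshoot; the `raw` column reports
  # the raw estimate's own deviation from the true target for reference.
  dwell_periods <- unique(traj$period[traj$phase == "fixation"])
  post_motion <- dwell_periods[dwell_periods > 1]
  transients <- do.call(rbind, lapply(post_motion, function(pd) {
    ix <- which(traces$period == pd)
    dev_raw <- function(xs, ys) max(sqrt((xs - traces$raw_sx[ix])^2 +
                                           (ys - traces$raw_sy[ix])^2),
                                    na.rm = TRUE)
    data.frame(period = pd, point = traces$point[ix][1],
               raw = max(sqrt((traces$raw_sx[ix] - traces$true_sx[ix])^2 +
                                (traces$raw_sy[ix] - traces$true_sy[ix])^2),
                         na.rm = TRUE),
               kal_cv = dev_raw(traces$cv_sx[ix], traces$cv_sy[ix]),
               kal_ca = dev_raw(traces$ca_sx[ix], traces$ca_sy[ix]))
  }))
  structure(list(version = "1.0", task = "saccade", seed = config$seed,
                 rendered = render, model = model,
                 traces = traces, transients = transients,
                 estimates = est, observations = task_obs),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %s task (seed %d, %s)\n", x$task, x$seed,
              if (x$rendered) "rendered frames" else "parameter-level"))
  if (!is.null(x$overall)) {
    cat("overall error statistics (screen px / px^2):\n")
    print(x$overall, row.names = FALSE)
  }
  if (!is.null(x$transients)) {
    cat("transient amplitudes at post-motion dwells (screen px):\n")
    print(x$transients, row.names = FALSE)
  }
  invisible(x)
}

#' Write / read frames as 8-bit grayscale PNG files
#'
#' Files are named `frame_000000.png` etc., in frame order.
#'
#' @param frames list of grayscale matrices (0-255).
#' @param dir output directory (created if needed).
#' @return `write_frames_png` returns the file paths; `read_frames_png`
#'   returns a list of matrices.
#' @export
write_frames_png <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_along(frames) - 1))
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]] / 255, paths[i])
  }
  invisible(paths)
}

#' @rdname write_frames_png
#' @param dir directory of PNG frames.
#' @export
read_frames_png <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 3) a <- a[, , 1]
    round(a * 255)
  })
}

#' Serialize an evaluation report to JSON
#'
#' Writes the metric tables (not the bulky per-frame estimates) with full
#' numeric precision.
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  out <- list(version = report$version, task = report$task,
              seed = report$seed, rendered = report$rendered,
              overall = report$overall, per_point = report$per_point,
              precision = report$precision, transients = report$transients,
              calibration_residual = report$model$residual)
  out <- out[!vapply(out, is.null, TRUE)]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
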