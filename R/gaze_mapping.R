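# Second-order polynomial gaze mapping (PCCR model).
#
# Calibration regresses each screen coordinate on the 6-term quadratic basis
# (1, vx, vy, vx*vy, vx^2, vy^2) of the pupil-corneal-reflection vector,
# the canonical second-order polynomial model for pupil-corneal-reflection
# gaze estimation. With the standard 9-point grid the system is
# overdetermined and solved by least squares (QR); the RMS calibration
# residual is reported.

quad_design <- function(vx, vy) {
  cbind(1, vx, vy, vx * vy, vx^2, vy^2)
}

#' Calibrate the PCR-to-screen polynomial map
#'
#' @param pcr matrix/data.frame with columns vx, vy: one aggregated PCR
#'   vector per calibration point (use [aggregate_calibration()] to reduce
#'   per-frame observations to per-point medians first).
#' @param screen_points data.frame with columns sx, sy (same row order).
#' @param screen_size numeric (width, height), pixels (metadata).
#' @return object of class `mapping_model`: `coeffs_x`, `coeffs_y` (length-6
#'   each), `screen_size`, `residual` (RMS calibration residual, px),
#'   `condition` (design condition number).
#' @export
calibrate_mapping <- function(pcr, screen_points,
                              screen_size = c(1280, 720)) {
  pcr <- as.data.frame(pcr)
  if (nrow(pcr) < 6) stop("at least 6 calibration points are required")
  if (nrow(pcr) != nrow(as.data.frame(screen_points))) {
    stop("pcr and screen_points must have the same number of rows")
  }
  B <- quad_design(pcr$vx, pcr$vy)
  qrB <- qr(B)
  if (qrB$rank < 6) stop("rank-deficient calibration design")
  cond <- kappa(B, exact = TRUE)
  if (cond > 1e8) {
    warning("ill-conditioned calibration design (condition number > 1e8)")
  }
  cx <- qr.coef(qrB, screen_points$sx)
  cy <- qr.coef(qrB, screen_points$sy)
  fit <- cbind(B %*% cx, B %*% cy)
  res <- sqrt(mean((fit[, 1] - screen_points$sx)^2 +
                     (fit[, 2] - screen_points$sy)^2))
  structure(list(coeffs_x = as.numeric(cx), coeffs_y = as.numeric(cy),
                 screen_size = as.numeric(screen_size),
                 residual = res, condition = cond),
            class = "mapping_model")
}

#' Median-aggregate per-frame PCR observations per calibration point
#'
#' The per-point median over the fixation window is robust to blink frames
#' and extraction outliers.
#'
#' @param obs data.frame with columns `point`, `vx`, `vy` (and optionally
#'   `valid`).
#' @return data.frame: `point`, `vx`, `vy`, `n` (frames used).
#' @export
aggregate_calibration <- function(obs) {
  if (!is.null(obs$valid)) obs <- obs[obs$valid & !is.na(obs$vx), ]
  sp <- split(obs, obs$point)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(point = d$point[1], vx = stats::median(d$vx),
               vy = stats::median(d$vy), n = nrow(d))
  }))
  out[order(out$point), ]
}

#' Map PCR vectors to screen points of regard
#'
#' Evaluates both calibrated polynomials. No clipping is applied: estimated
#' PORs may fall off-screen and are reported as-is.
#'
#' @param model a `mapping_model` from [calibrate_mapping()].
#' @param pcr matrix/data.frame with columns vx, vy (or a length-2 vector).
#' @return data.frame with columns `sx`, `sy`.
#' @export
map_por <- function(model, pcr) {
  if (is.numeric(pcr) && is.null(dim(pcr))) {
    pcr <- data.frame(vx = pcr[1], vy = pcr[2])
  }
  pcr <- as.data.frame(pcr)
  B <- quad_design(pcr$vx, pcr$vy)
  data.frame(sx = as.numeric(B %*% model$coeffs_x),
             sy = as.numeric(B %*% model$coeffs_y))
}

#' Local Jacobian of the gaze map
#'
#' The 2x2 derivative of screen coordinates with respect to the PCR vector at
#' a given point; its singular values quantify how strongly small PCR
#' perturbations are amplified on screen.
#'
#' @param model a `mapping_model`.
#' @param pcr numeric (vx, vy).
#' @return 2x2 Jacobian matrix.
#' @export
mapping_jacobian <- function(model, pcr) {
  vx <- pcr[1]; vy <- pcr[2]
  dB_dvx <- c(0, 1, 0, vy, 2 * vx, 0)
  dB_dvy <- c(0, 0, 1, vx, 0, 2 * vy)
  matrix(c(sum(dB_dvx * model$coeffs_x), sum(dB_dvy * model$coeffs_x),
           sum(dB_dvx * model$coeffs_y), sum(dB_dvy * model$coeffs_y)),
         2, 2, byrow = TRUE)
}

#' Serialize / restore a mapping model as JSON
#'
#' @param model a `mapping_model`.
#' @param path output/input file path.
#' @return `read_mapping_model` returns a `mapping_model`.
#' @export
write_mapping_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mapping_model
#' @export
read_mapping_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m[c("coeffs_x", "coeffs_y", "screen_size", "residual",
                "condition")], class = "mapping_model")
}
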