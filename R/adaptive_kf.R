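# Velocity-adaptive Kalman filtering of the PCR vector.
#
# A linear Kalman filter with a constant-velocity (CV, 4-state) or
# constant-acceleration (CA, 6-state) kinematic model smooths the per-frame
# pupil-corneal-reflection vector before gaze mapping. The measurement-noise
# covariance R_k is not constant: a speed proxy built from the inter-frame
# eye-image difference (gated through a logistic function) and the gaze-point
# displacement drives R_k up to R_max when the gaze moves, and lets it decay
# geometrically (blend weight w_R) back toward R_min when the gaze settles.
# Frames with no usable measurement (blink, lost glint) advance by prediction
# only, which is exactly equivalent to taking the measurement equal to the
# predicted measurement.

#' Kinematic filter model
#'
#' @param type `"cv"` (state `[x, y, vx, vy]`) or `"ca"`
#'   (state `[x, y, vx, vy, ax, ay]`).
#' @param dt frame interval; 1 for frame-to-frame tracking.
#' @param q process-noise scale; `Q = q * I`.
#' @param printed_ca use the 4-state constant-acceleration transition in its
#'   published 4x4 form (which couples x-position to y-velocity) instead of
#'   the standard 6-state model. Compatibility option; off by default.
#' @param printed_h use the measurement matrix in its published form
#'   (measurement = position + velocity) instead of position-only selection.
#'   Compatibility option; off by default.
#' @return list of class `kf_model`: `A`, `H`, `Q`, `dim`, `type`, `dt`.
#' @export
kf_model <- function(type = c("cv", "ca"), dt = 1, q = 1e-3,
                     printed_ca = FALSE, printed_h = FALSE) {
  type <- match.arg(type)
  if (type == "cv" || printed_ca) {
    n <- 4L
    if (type == "cv") {
      A <- diag(4)
      A[1, 3] <- dt; A[2, 4] <- dt
    } else {
      # published 4x4 constant-acceleration form
      A <- diag(4)
      A[1, 3] <- dt; A[1, 4] <- dt^2 / 2; A[2, 4] <- dt
    }
  } else {
    n <- 6L
    A <- diag(6)
    A[1, 3] <- dt; A[1, 5] <- dt^2 / 2
    A[2, 4] <- dt; A[2, 6] <- dt^2 / 2
    A[3, 5] <- dt; A[4, 6] <- dt
  }
  H <- matrix(0, 2, n)
  H[1, 1] <- 1; H[2, 2] <- 1
  if (printed_h) {
    H[1, 3] <- 1; H[2, 4] <- 1
  }
  structure(list(A = A, H = H, Q = q * diag(n), dim = n, type = type,
                 dt = dt),
            class = "kf_model")
}

#' Initialize a filter state from the first measurement
#'
#' The position components are set equal to the observed value (so the first
#' filtered output reproduces the raw observation exactly) and all derivative
#' components to zero.
#'
#' @param z numeric (x, y) first measurement.
#' @param model a [kf_model()].
#' @param R0 initial measurement-noise scale (also used for the position
#'   block of the initial covariance).
#' @return list of class `kf_state`: `x`, `P`, `R`, `K`, `innovation`.
#' @export
kf_init_state <- function(z, model, R0 = 0.01) {
  x <- numeric(model$dim)
  x[1:2] <- z
  P <- diag(model$dim)
  P[1, 1] <- P[2, 2] <- R0
  structure(list(x = x, P = P, R = R0, K = NULL,
                 innovation = c(0, 0)),
            class = "kf_state")
}

symmetrize <- function(P) (P + t(P)) / 2

#' Kalman prediction step
#'
#' `x_pred = A x`, `P_pred = A P A' + Q`.
#'
#' @param state a `kf_state`.
#' @param model a [kf_model()].
#' @return predicted `kf_state`.
#' @export
kf_predict <- function(state, model) {
  state$x <- as.numeric(model$A %*% state$x)
  state$P <- symmetrize(model$A %*% state$P %*% t(model$A) + model$Q)
  state
}

#' Kalman correction step
#'
#' Standard gain/update equations with scalar measurement-noise scale `R`
#' (used as `R * I2`): `K = P H'(H P H' + R)^-1`,
#' `x = x + K (z - H x)`, `P = (I - K H) P`.
#'
#' @param state predicted `kf_state` (from [kf_predict()]).
#' @param z numeric (x, y) measurement.
#' @param model a [kf_model()].
#' @param R measurement-noise scale for this step; defaults to the scale
#'   stored in the state.
#' @return corrected `kf_state` (with `K`, `innovation`, `R` updated).
#' @export
kf_correct <- function(state, z, model, R = NULL) {
  R <- R %||% state$R
  H <- model$H
  S <- H %*% state$P %*% t(H) + R * diag(2)
  if (!is.finite(rcond(S)) || rcond(S) < .Machine$double.eps) {
    stop("singular innovation covariance")
  }
  K <- state$P %*% t(H) %*% solve(S)
  innov <- z - as.numeric(H %*% state$x)
  state$x <- state$x + as.numeric(K %*% innov)
  state$P <- symmetrize((diag(model$dim) - K %*% H) %*% state$P)
  state$K <- K
  state$innovation <- innov
  state$R <- R
  state
}

#' Missing-measurement step
#'
#' When no measurement is available the state is advanced by prediction only
#' (equivalently, the measurement is assumed equal to the predicted
#' measurement, so the correction is a no-op).
#'
#' @param state a `kf_state`.
#' @param model a [kf_model()].
#' @return predicted `kf_state` (identical to [kf_predict()] output).
#' @export
kf_step_missing <- function(state, model) {
  state <- kf_predict(state, model)
  state$K <- NULL
  state$innovation <- c(NA_real_, NA_real_)
  state
}

#' Inter-frame eye-image difference (motion energy)
#'
#' Sum of squared per-pixel intensity differences between two consecutive
#' cropped eye images of identical shape. Intensities are expected on the
#' [0, 1] scale (divide 8-bit crops by 255).
#'
#' @param frame_t,frame_t_minus_1 numeric matrices of identical dim.
#' @return scalar m >= 0.
#' @export
eye_difference <- function(frame_t, frame_t_minus_1) {
  if (!all(dim(frame_t) == dim(frame_t_minus_1))) {
    stop("cropped frames must have identical shape")
  }
  sum((frame_t - frame_t_minus_1)^2)
}

#' Logistic motion gate
#'
#' Maps the raw motion energy `m` into (0, 1):
#' `S = 1 / (1 + exp(-beta_m (m - alpha_m)))`.
#'
#' @param m motion energy (from [eye_difference()]).
#' @param alpha_m logistic midpoint (> 0).
#' @param beta_m logistic steepness (> 0).
#' @return gate value in (0, 1).
#' @export
logistic_gate <- function(m, alpha_m, beta_m) {
  if (beta_m <= 0) stop("beta_m must be positive")
  1 / (1 + exp(-beta_m * (m - alpha_m)))
}

#' Gated gaze velocity
#'
#' The gaze-point displacement scaled by the motion gate:
#' `v = S * (q_t - q_{t-1})`.
#'
#' @param S motion gate in (0, 1) (from [logistic_gate()]); 1 disables
#'   gating.
#' @param q_t,q_t_minus_1 numeric (x, y) gaze points of the current and
#'   previous frame.
#' @return numeric (vx, vy).
#' @export
gaze_velocity <- function(S, q_t, q_t_minus_1) {
  S * (q_t - q_t_minus_1)
}

#' Adaptive measurement-noise configuration
#'
#' @param R_max maximal measurement-noise scale (must exceed the process
#'   noise scale).
#' @param R_min floor of the measurement-noise scale (> 0).
#' @param w_R blend weight in (0, 1) for the slow decay branch.
#' @param L look-back window (number of recent speed scalars whose maximum
#'   drives the candidate noise level).
#' @param alpha_m,beta_m logistic motion-gate parameters.
#' @param v_scale speed normalization constant (px/frame); `NULL` means
#'   "estimate from the data" (95th percentile of observed speeds).
#' @param inverse_adaptation if `TRUE`, invert the speed-to-noise relation so
#'   that faster gaze yields a *smaller* measurement covariance (i.e. the
#'   measurement is trusted more during movement, as the motivating prose
#'   suggests, whereas the published equations increase R with speed).
#'   Off by default: the equations are implemented as published.
#' @return list of class `adaptive_config`.
#' @export
adaptive_config <- function(R_max = 0.04, R_min = 0.01 * R_max, w_R = 0.3,
                            L = 5, alpha_m = 2, beta_m = 1, v_scale = NULL,
                            inverse_adaptation = FALSE) {
  stopifnot(R_max > 0, R_min > 0, R_min <= R_max, w_R > 0, w_R < 1, L >= 1,
            alpha_m > 0, beta_m > 0)
  structure(list(R_max = R_max, R_min = R_min, w_R = w_R, L = L,
                 alpha_m = alpha_m, beta_m = beta_m, v_scale = v_scale,
                 inverse_adaptation = inverse_adaptation),
            class = "adaptive_config")
}

#' Speed-adaptive measurement-noise update
#'
#' The candidate level is `R_tilde = R_max * max(speeds)` over the last
#' `L + 1` normalized speed scalars (in [0, 1]). If the candidate is below
#' the previous level the noise decays slowly,
#' `R = w_R * R_tilde + (1 - w_R) * R_prev`; otherwise it rises instantly to
#' the candidate. The result is floored at `R_min`.
#'
#' @param R_prev previous measurement-noise scale.
#' @param speeds numeric vector of recent normalized speed scalars.
#' @param config an [adaptive_config()].
#' @return updated scalar measurement-noise scale.
#' @export
update_R <- function(R_prev, speeds, config) {
  s <- max(speeds, 0)
  if (isTRUE(config$inverse_adaptation)) s <- 1 - s
  R_tilde <- config$R_max * s
  R <- if (R_tilde < R_prev) {
    config$w_R * R_tilde + (1 - config$w_R) * R_prev
  } else {
    R_tilde
  }
  max(R, config$R_min)
}

#' Filter an observation sequence with the adaptive Kalman filter
#'
#' Initializes the state from the first valid observation (the first filtered
#' output equals the raw observation), then iterates
#' predict -> noise adaptation -> correct, routing missing frames through the
#' prediction-only step. The speed proxy uses the *raw* gaze points of the
#' previous two frames (pre-filter), so the adaptation never feeds back the
#' filter's own lag; when per-frame motion energies `m` are present they gate
#' the displacement through the logistic function, otherwise the gate is 1.
#'
#' @param obs data.frame with columns `vx`, `vy` (measured PCR vector) and
#'   optionally `missing` (logical) and `m` (motion energy from
#'   [eye_difference()]).
#' @param model_type `"cv"` or `"ca"`.
#' @param config an [adaptive_config()].
#' @param model optional [kf_model()] override (e.g. with compatibility
#'   flags); must match `model_type`.
#' @param gaze_points optional n x 2 matrix of raw gaze points driving the
#'   speed proxy (defaults to the raw measurements themselves).
#' @return data.frame: `frame`, `vx`, `vy` (filtered), `R`, `speed`,
#'   `innovation_x`, `innovation_y`, `missing`.
#' @export
filter_sequence <- function(obs, model_type = c("cv", "ca"),
                            config = adaptive_config(), model = NULL,
                            gaze_points = NULL) {
  model_type <- match.arg(model_type)
  model <- model %||% kf_model(model_type)
  n <- nrow(obs)
  missing <- if (!is.null(obs[["missing"]])) obs[["missing"]] | is.na(obs$vx)
             else is.na(obs$vx)
  q <- if (!is.null(gaze_points)) as.matrix(gaze_points)
       else cbind(obs$vx, obs$vy)
  m <- obs[["m"]]  # exact match: $ would partially match "missing" 

  # normalized speed scalar per frame from raw gaze-point displacements
  dq <- rbind(c(0, 0), diff(q))
  dq[is.na(dq)] <- 0
  S <- if (!is.null(m)) {
    logistic_gate(ifelse(is.na(m), 0, m), config$alpha_m, config$beta_m)
  } else rep(1, n)
  vmag <- sqrt(rowSums((S * dq)^2))
  v_scale <- config$v_scale %||%
    max(as.numeric(stats::quantile(vmag[-1], 0.95, na.rm = TRUE)), 1e-9)
  speed <- clip01(vmag / v_scale)

  out <- data.frame(frame = if (!is.null(obs[["frame"]])) obs[["frame"]]
                            else seq_len(n) - 1L,
                    vx = NA_real_, vy = NA_real_, R = NA_real_,
                    speed = speed, innovation_x = NA_real_,
                    innovation_y = NA_real_, missing = missing)
  first <- which(!missing)[1]
  if (is.na(first)) stop("no valid observation in the sequence")
  state <- kf_init_state(c(obs$vx[first], obs$vy[first]), model,
                         R0 = config$R_min)
  out$vx[first] <- obs$vx[first]
  out$vy[first] <- obs$vy[first]
  out$R[first] <- state$R
  if (first < n) {
    for (i in (first + 1):n) {
      win <- speed[max(first, i - config$L):i]
      R_i <- update_R(state$R, win, config)
      if (missing[i]) {
        state <- kf_step_missing(state, model)
        state$R <- R_i
      } else {
        state <- kf_predict(state, model)
        state <- kf_correct(state, c(obs$vx[i], obs$vy[i]), model, R = R_i)
      }
      out$vx[i] <- state$x[1]
      out$vy[i] <- state$x[2]
      out$R[i] <- R_i
      out$innovation_x[i] <- state$innovation[1]
      out$innovation_y[i] <- state$innovation[2]
    }
  }
  out
}
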