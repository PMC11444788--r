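# Constant-velocity Kalman filter on bounding boxes, parameterized as
# (cx, cy, a, h): box center, aspect ratio a = width/height, and height.
# The 8-dimensional state appends the per-frame velocities of the four
# measured quantities. Process and measurement noise scale with the box
# height h, a standard convention for pixel-space trackers: position noise
# std = h * std_weight_pos per frame, velocity noise std = h * std_weight_vel.
# For very small targets the height-scaled terms collapse below the pixel
# scale, so absolute floors are applied: detection jitter and maneuvering
# acceleration are properties of the imaging and the flight, not of the
# body size. The aspect ratio of a rotating elongated body swings between
# w/l and l/w, so the aspect terms are far noisier than in the
# fixed-upright-target convention.

KF_POS_FLOOR <- 1.0   # px, process + measurement position noise floor
KF_VEL_FLOOR <- 0.4   # px/frame, process velocity noise floor
KF_ASPECT_Q <- 0.25   # per-frame process noise on aspect ratio
KF_ASPECT_R <- 0.80   # measurement noise on aspect ratio
KF_SIZE_Q <- 2.0      # px, process noise floor on box height
KF_SIZE_R <- 2.5      # px, measurement noise floor on box height

#' Convert a bounding box to the (cx, cy, a, h) measurement vector
#'
#' @param box A box (vector or 1 x 4 matrix).
#' @return Numeric vector `c(cx, cy, a, h)` where `a = width / height`.
#' @export
box_to_xyah <- function(box) {
  b <- as_box_matrix(box)
  w <- b[, 3] - b[, 1]; h <- b[, 4] - b[, 2]
  c(cx = (b[, 1] + b[, 3]) / 2, cy = (b[, 2] + b[, 4]) / 2,
    a = if (h > 0) w / h else 1, h = h)
}

#' Convert a (cx, cy, a, h) vector back to a bounding box
#'
#' @param xyah Numeric vector `c(cx, cy, a, h)`.
#' @return A 1 x 4 box matrix.
#' @export
xyah_to_box <- function(xyah) {
  w <- xyah[3] * xyah[4]; h <- xyah[4]
  bbox(xyah[1] - w / 2, xyah[2] - h / 2, xyah[1] + w / 2, xyah[2] + h / 2)
}

#' Initialize a Kalman state from a first measurement
#'
#' The position block is set to the measurement, velocities to zero, and the
#' initial covariance is diagonal with generous (height-scaled) uncertainty
#' on the unobserved velocities.
#'
#' @param xyah First measurement `c(cx, cy, a, h)`.
#' @param std_weight_pos,std_weight_vel Noise scale relative to box height.
#' @return A list with elements `mean` (length 8) and `cov` (8 x 8).
#' @export
kf_init <- function(xyah, std_weight_pos = 1 / 20, std_weight_vel = 1 / 160) {
  h <- xyah[4]
  sp <- max(std_weight_pos * h, KF_POS_FLOOR)
  sv <- max(std_weight_vel * h, KF_VEL_FLOOR)
  mean <- c(xyah, rep(0, 4))
  sh <- max(std_weight_pos * h, KF_SIZE_Q)
  std <- c(2 * sp, 2 * sp, 2 * KF_ASPECT_Q, 2 * sh,
           10 * sv, 10 * sv, KF_ASPECT_Q, 10 * sv)
  list(mean = unname(mean), cov = diag(std^2),
       wp = std_weight_pos, wv = std_weight_vel)
}

kf_transition <- function() {
  F <- diag(8)
  F[cbind(1:4, 5:8)] <- 1
  F
}

#' Predict one frame ahead
#'
#' Constant-velocity propagation: positions advance by their velocities and
#' the covariance is inflated by height-scaled process noise, so uncertainty
#' grows monotonically while a track coasts without detections.
#'
#' @param state Kalman state from [kf_init()], [kf_predict()] or
#'   [kf_update()].
#' @return The propagated state.
#' @export
kf_predict <- function(state) {
  F <- kf_transition()
  h <- state$mean[4]
  sp <- max(state$wp * h, KF_POS_FLOOR)
  sv <- max(state$wv * h, KF_VEL_FLOOR)
  sh <- max(state$wp * h, KF_SIZE_Q)
  std <- c(sp, sp, KF_ASPECT_Q, sh, sv, sv, KF_ASPECT_Q / 3, sv)
  state$mean <- as.vector(F %*% state$mean)
  state$cov <- F %*% state$cov %*% t(F) + diag(std^2)
  state
}

# Project the state into measurement space: returns the predicted
# measurement z (length 4) and innovation covariance S (4 x 4, includes
# height-scaled measurement noise).
kf_project <- function(state) {
  h <- state$mean[4]
  sp <- max(state$wp * h, KF_POS_FLOOR)
  sh <- max(state$wp * h, KF_SIZE_R)
  std <- c(sp, sp, KF_ASPECT_R, sh)
  list(z = state$mean[1:4],
       S = state$cov[1:4, 1:4] + diag(std^2))
}

#' Kalman measurement update
#'
#' Standard linear update: with gains in (0, 1) the posterior position lies
#' componentwise between the prediction and the measurement.
#'
#' @param state Kalman state (after [kf_predict()]).
#' @param xyah Measurement `c(cx, cy, a, h)`; must be finite.
#' @return The updated state.
#' @export
kf_update <- function(state, xyah) {
  xyah <- unname(as.numeric(xyah))
  if (length(xyah) != 4 || !all(is.finite(xyah)))
    stop("measurement must be 4 finite numbers (cx, cy, a, h)")
  pr <- kf_project(state)
  K <- state$cov[, 1:4] %*% solve(pr$S)
  innov <- xyah - pr$z
  state$mean <- as.vector(state$mean + K %*% innov)
  cov <- state$cov - K %*% state$cov[1:4, ]
  state$cov <- (cov + t(cov)) / 2
  state
}

# Squared Mahalanobis distance of an innovation y under covariance S.
maha_sq <- function(y, S) {
  sol <- tryCatch(solve(S, y), error = function(e)
    stop("singular innovation covariance"))
  as.numeric(crossprod(y, sol))
}

#' Squared Mahalanobis distance of a measurement from the predicted state
#'
#' Measures motion consistency: how many (squared) standard deviations the
#' measurement lies from the predicted measurement distribution. Used to
#' gate the association cost matrix at a chi-square quantile (4 degrees of
#' freedom).
#'
#' @param state Kalman state (after [kf_predict()]).
#' @param xyah Measurement `c(cx, cy, a, h)`.
#' @return Non-negative scalar.
#' @export
kf_mahalanobis_sq <- function(state, xyah) {
  pr <- kf_project(state)
  maha_sq(unname(as.numeric(xyah)) - pr$z, pr$S)
}
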