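#' Observer gain schedule for tilt estimation
#'
#' The observer corrects a gyro-integrated tilt estimate toward the
#' accelerometer-derived tilt with a gain that switches by regime: the
#' accelerometer is trusted (high gain) while the measured acceleration
#' magnitude stays within `accel_switch` of gravity, and the gyroscope
#' is trusted (low gain) during high dynamics.  Gains are per-step
#' corrections on the sampling grid; the bias-estimator gain is tied to
#' the tilt gain by `k_bias_ratio`.
#'
#' @param k_theta_high Tilt gain in the accel-trusting (quiet) regime.
#' @param k_theta_low Tilt gain in the gyro-trusting (dynamic) regime.
#' @param k_bias_ratio Bias gain as a fraction of the active tilt gain.
#' @param accel_switch Regime threshold on `| ||a|| - g |`, m/s^2.
#' @return A list of class `tilt_gains`.
#' @export
tilt_gains <- function(k_theta_high = 0.02, k_theta_low = 0.002,
                       k_bias_ratio = 0.1, accel_switch = 1.5) {
  if (k_theta_high <= 0 || k_theta_low <= 0 || k_bias_ratio <= 0 ||
      accel_switch <= 0)
    abort("observer gains and switch threshold must be positive",
          class = "nearfallr_validation_error")
  structure(list(k_theta_high = k_theta_high, k_theta_low = k_theta_low,
                 k_bias_ratio = k_bias_ratio, accel_switch = accel_switch),
            class = "tilt_gains")
}

check_uniform_grid <- function(t) {
  if (length(t) < 2)
    abort("trace too short for tilt estimation",
          class = "nearfallr_validation_error")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    abort("tilt estimation requires a uniform sampling grid; assemble the session first",
          class = "nearfallr_precondition_error")
  mean(dt)
}

#' Estimate segment tilt and gyro bias with a switched-gain observer
#'
#' Discrete observer on the sampling grid:
#' \deqn{\hat\theta_{k+1} = \hat\theta_k + \Delta t\,(\omega_k - \hat b_k)
#'   + K_\theta(k)\,(\theta_{acc,k} - \hat\theta_k)}
#' \deqn{\hat b_{k+1} = \hat b_k - K_b(k)\,(\theta_{acc,k} - \hat\theta_k)}
#' where \eqn{\theta_{acc} = \mathrm{atan2}(a_x, a_z)} is the
#' accelerometer tilt and \eqn{\omega} the pitch-axis gyro.  The gain
#' schedule fuses the accelerometer at low frequencies and the gyro at
#' high frequencies (see [tilt_gains()]); the constant gyro bias is
#' estimated and removed along the way.  Only sagittal (pitch) tilt is
#' estimated, matching the in-plane walking geometry of the array.
#'
#' @param x An [imu_trace()] on a uniform grid, or a
#'   `session_recording`.
#' @param gains A [tilt_gains()] schedule.
#' @param theta0 Initial tilt estimate; default = accelerometer tilt at
#'   the first sample.
#' @param b0 Initial bias estimate (rad/s), default 0.
#' @param ... Passed to methods.
#' @return For a trace: a tibble with columns `t`, `theta` (rad),
#'   `bias` (rad/s), `theta_acc` (raw accelerometer tilt).  For a
#'   session: a `tilt_series` tibble `t` + one tilt column per
#'   placement, with the final per-placement bias estimates in
#'   `attr(, "gyro_bias")`.
#' @export
estimate_tilt <- function(x, gains = tilt_gains(), ...) {
  UseMethod("estimate_tilt")
}

#' @rdname estimate_tilt
#' @export
estimate_tilt.imu_trace <- function(x, gains = tilt_gains(),
                                    theta0 = NULL, b0 = 0, ...) {
  stopifnot(inherits(gains, "tilt_gains"))
  dt <- check_uniform_grid(x$t)
  n <- nrow(x)
  theta_acc <- atan2(x$ax, x$az)
  a_mag <- sqrt(x$ax^2 + x$ay^2 + x$az^2)
  quiet <- abs(a_mag - GRAVITY) <= gains$accel_switch
  k_theta <- ifelse(quiet, gains$k_theta_high, gains$k_theta_low)
  k_bias <- k_theta * gains$k_bias_ratio

  theta <- numeric(n)
  bias <- numeric(n)
  theta[1] <- theta0 %||% theta_acc[1]
  bias[1] <- b0
  omega <- x$gy
  for (k in seq_len(n - 1)) {
    innov <- theta_acc[k] - theta[k]
    theta[k + 1] <- theta[k] + dt * (omega[k] - bias[k]) + k_theta[k] * innov
    bias[k + 1] <- bias[k] - k_bias[k] * innov
  }
  # keep the estimate on the principal branch
  theta <- ((theta + pi) %% (2 * pi)) - pi
  tibble(t = x$t, theta = theta, bias = bias, theta_acc = theta_acc)
}

#' @rdname estimate_tilt
#' @export
estimate_tilt.session_recording <- function(x, gains = tilt_gains(), ...) {
  per <- purrr::map(x$traces, estimate_tilt, gains = gains, ...)
  out <- tibble(t = per[[1]]$t)
  for (p in names(per)) out[[p]] <- per[[p]]$theta
  structure(out,
            class = c("tilt_series", class(tibble())),
            gyro_bias = purrr::map_dbl(per, ~ tail(.x$bias, 1)),
            gains = gains)
}
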