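#' Default activity mix and mean durations for simulated home sessions
#'
#' The mix emulates daytime home activity of ambulatory movement-disorder
#' patients: mostly walking, standing and turning, regular sitting,
#' occasional bends and lie-downs, and rare balance events.  Transitions
#' (`stand_to_sit`, `sit_to_stand`) are never drawn directly; the script
#' grammar inserts them wherever posture changes.
#'
#' @return Named numeric vector (probabilities summing to 1, or mean
#'   segment durations in seconds).
#' @export
default_class_mix <- function() {
  c(stand = 0.23, walk = 0.30, turn = 0.14, sit = 0.12, bend = 0.08,
    lie_down = 0.05, near_fall = 0.06, fall = 0.02)
}

#' @rdname default_class_mix
#' @export
default_mean_durations <- function() {
  c(stand = 8, walk = 12, turn = 4, sit = 20, bend = 3, lie_down = 15,
    near_fall = 1.8, fall = 2, stand_to_sit = 1.5, sit_to_stand = 1.5)
}

#' Sensor noise model for the simulator
#'
#' White measurement noise on both modalities plus a constant
#' per-session, per-axis gyroscope bias drawn uniformly from
#' `[-bias_range, bias_range]`.
#'
#' @param accel_sd Accelerometer noise sd, m/s^2.
#' @param gyro_sd Gyroscope noise sd, rad/s.
#' @param bias_range Half-width of the uniform gyro-bias draw, rad/s.
#' @param seed Optional integer seed for the stochastic draws.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(accel_sd = 0.3, gyro_sd = 0.02, bias_range = 0.05,
                        seed = NULL) {
  if (accel_sd < 0 || gyro_sd < 0 || bias_range < 0)
    abort("noise standard deviations must be >= 0",
          class = "nearfallr_validation_error")
  structure(list(accel_sd = accel_sd, gyro_sd = gyro_sd,
                 bias_range = bias_range, seed = seed),
            class = "noise_model")
}

draw_duration <- function(class, mean_durations, sdlog = 0.35) {
  m <- mean_durations[[class]]
  d <- rlnorm(1, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  if (class %in% c("stand_to_sit", "sit_to_stand")) d <- min(max(d, 0.5), 5)
  if (class == "near_fall") d <- min(max(d, 1.2), 3)
  if (class == "fall") d <- min(max(d, 1.2), 4)
  d
}

draw_cadence <- function(class) {
  switch(class,
         walk = runif(1, 0.8, 1.2),
         turn = runif(1, 1.4, 1.8),
         NA_real_)
}

#' Generate a random activity script
#'
#' Draws a sequence of activity segments from `class_mix` until the
#' cumulative duration reaches `total_duration`, inserting posture
#' transitions so that every entry into `sit` passes through
#' `stand_to_sit` and every exit through `sit_to_stand`, and so that a
#' `fall` is followed by a sustained `lie_down`.  Segment durations are
#' log-normal around the class means; gait segments carry a scripted
#' cadence (walk 0.8-1.2 Hz, turn 1.4-1.8 Hz).
#'
#' @param total_duration Target session length, seconds.
#' @param class_mix Named probabilities over non-transition classes
#'   (must sum to 1 within 1e-9).
#' @param mean_durations Named mean durations, seconds (all positive).
#' @param seed Optional integer seed; with a fixed seed the script is
#'   reproducible.
#' @return A tibble of class `activity_script` with columns `activity`,
#'   `duration`, `cadence`.
#' @export
generate_random_script <- function(total_duration = 600,
                                   class_mix = default_class_mix(),
                                   mean_durations = default_mean_durations(),
                                   seed = NULL) {
  if (abs(sum(class_mix) - 1) > 1e-9)
    abort("class_mix probabilities must sum to 1",
          class = "nearfallr_validation_error")
  if (any(mean_durations <= 0) || total_duration <= 0)
    abort("durations must be positive", class = "nearfallr_validation_error")
  if (any(!names(class_mix) %in% activity_classes()))
    abort("class_mix names must be activity classes",
          class = "nearfallr_validation_error")
  md <- default_mean_durations()
  md[names(mean_durations)] <- mean_durations

  run <- function() {
    acts <- character(0); durs <- numeric(0); cads <- numeric(0)
    posture <- "upright"  # upright | seated
    total <- 0
    push <- function(a, d, cad = NA_real_) {
      acts[length(acts) + 1] <<- a
      durs[length(durs) + 1] <<- d
      cads[length(cads) + 1] <<- cad
      total <<- total + d
    }
    while (total < total_duration) {
      nxt <- sample(names(class_mix), 1, prob = class_mix)
      if (posture == "seated" && nxt != "sit")
        push("sit_to_stand", draw_duration("sit_to_stand", md))
      if (posture == "upright" && nxt == "sit")
        push("stand_to_sit", draw_duration("stand_to_sit", md))
      posture <- if (nxt == "sit") "seated" else "upright"
      push(nxt, draw_duration(nxt, md), draw_cadence(nxt))
      if (nxt == "fall") {
        # a fall ends on the ground: sustained lying before recovery
        push("lie_down", max(draw_duration("lie_down", md) / 2, 4))
        posture <- "upright"
      }
    }
    # trim the final segment so the script sums to total_duration
    excess <- total - total_duration
    last <- length(durs)
    if (durs[last] - excess >= 0.3) {
      durs[last] <- durs[last] - excess
    } else if (last > 1) {
      acts <- acts[-last]; durs <- durs[-last]; cads <- cads[-last]
    }
    structure(tibble(activity = as_activity(acts), duration = durs,
                     cadence = cads),
              class = c("activity_script", class(tibble())))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# on/off envelope easing oscillations in and out of a segment
seg_envelope <- function(tau, d, r = 0.3) {
  r <- min(r, d / 3)
  pmin(1, tau / r, (d - tau) / r)
}

sway <- function(tau, d, amp = 0.015, f = 0.3) {
  amp * seg_envelope(tau, d) * sin(2 * pi * f * tau)
}

# Per-activity sagittal kinematics.  Returns theta (n x 5), lin (n x 5,
# axial linear-acceleration envelope) and yaw (n) for local time tau.
segment_kinematics <- function(activity, tau, d, cadence, prev) {
  n <- length(tau)
  pl <- sensor_placements()
  theta <- matrix(0, n, 5, dimnames = list(NULL, pl))
  lin <- matrix(0, n, 5, dimnames = list(NULL, pl))
  yaw <- numeric(n)
  env <- seg_envelope(tau, d)
  half <- sin(pi * tau / d)

  gait <- function(a_thigh, a_shank, a_chest, l_chest, l_leg, f) {
    ph <- 2 * pi * f * tau
    theta[, "thigh_l"] <<- a_thigh * env * sin(ph)
    theta[, "thigh_r"] <<- a_thigh * env * sin(ph + pi)
    theta[, "shank_l"] <<- a_shank * env * sin(ph - 0.4)
    theta[, "shank_r"] <<- a_shank * env * sin(ph - 0.4 + pi)
    theta[, "chest"] <<- a_chest * env * sin(2 * ph)
    lin[, "chest"] <<- l_chest * env * sin(2 * ph)
    lin[, "thigh_l"] <<- l_leg * env * sin(ph)
    lin[, "thigh_r"] <<- l_leg * env * sin(ph + pi)
    lin[, "shank_l"] <<- l_leg * env * sin(ph - 0.4)
    lin[, "shank_r"] <<- l_leg * env * sin(ph - 0.4 + pi)
  }

  if (activity == "stand") {
    for (p in pl) theta[, p] <- sway(tau, d)
  } else if (activity == "walk") {
    gait(0.35, 0.60, 0.05, 1.2, 1.5, cadence)
  } else if (activity == "turn") {
    gait(0.15, 0.28, 0.03, 0.8, 0.9, cadence)
    yaw <- 1.2 * env
  } else if (activity == "bend") {
    theta[, "chest"] <- (pi / 4) * half
    theta[, "thigh_l"] <- theta[, "thigh_r"] <- 0.12 * half
    lin[, "chest"] <- 0.6 * half
  } else if (activity == "stand_to_sit") {
    s <- smoothstep(tau / d)
    theta[, "thigh_l"] <- theta[, "thigh_r"] <- (pi / 2) * s
    theta[, "chest"] <- 0.35 * half
    lin[, "chest"] <- 1.0 * half
    lin[, "thigh_l"] <- lin[, "thigh_r"] <- 0.8 * half
  } else if (activity == "sit") {
    theta[, "thigh_l"] <- theta[, "thigh_r"] <- pi / 2 + 0.5 * sway(tau, d)
    theta[, "chest"] <- sway(tau, d)
    theta[, "shank_l"] <- theta[, "shank_r"] <- sway(tau, d)
  } else if (activity == "sit_to_stand") {
    s <- smoothstep(tau / d)
    theta[, "thigh_l"] <- theta[, "thigh_r"] <- (pi / 2) * (1 - s)
    theta[, "chest"] <- 0.45 * half
    lin[, "chest"] <- 1.4 * half
    lin[, "thigh_l"] <- lin[, "thigh_r"] <- 1.0 * half
  } else if (activity == "lie_down") {
    r_in <- if (identical(prev, "fall")) 0 else min(1.5, d / 3)
    r_out <- min(1.5, d / 3)
    base <- rep(pi / 2, n)
    if (r_in > 0) {
      ent <- tau < r_in
      base[ent] <- (pi / 2) * smoothstep(tau[ent] / r_in)
    }
    ext <- tau > d - r_out
    base[ext] <- pmin(base[ext], (pi / 2) * smoothstep((d - tau[ext]) / r_out))
    for (p in pl) theta[, p] <- base
    lin[, "chest"] <- 0.8 * half
  } else if (activity == "near_fall") {
    tp <- 0.5 * d
    g <- exp(-(tau - tp)^2 / (2 * 0.2^2))
    theta[, "chest"] <- 0.9 * g
    theta[, "thigh_l"] <- theta[, "thigh_r"] <- 0.25 * g
    theta[, "shank_l"] <- theta[, "shank_r"] <- 0.15 * g
    lin[, "chest"] <- 6.0 * exp(-(tau - tp)^2 / (2 * 0.12^2))
    lin[, "thigh_l"] <- lin[, "thigh_r"] <- 2.0 * g
    lin[, "shank_l"] <- lin[, "shank_r"] <- 1.5 * g
  } else if (activity == "fall") {
    t_chest <- min(0.7, d / 2)
    t_leg <- min(0.9, d / 1.5)
    theta[, "chest"] <- (pi / 2) * smoothstep(tau / t_chest)
    for (p in c("thigh_l", "thigh_r", "shank_l", "shank_r"))
      theta[, p] <- (pi / 2) * smoothstep(tau / t_leg)
    lin[, "chest"] <- 8.0 * exp(-((tau - t_chest) / 0.08)^2)
    for (p in c("thigh_l", "thigh_r", "shank_l", "shank_r"))
      lin[, p] <- 4.0 * exp(-((tau - t_leg) / 0.1)^2)
  }
  list(theta = theta, lin = lin, yaw = yaw)
}

#' Expand an activity script into per-segment tilt kinematics
#'
#' Produces the noise-free sagittal tilt trajectory of each of the five
#' body segments on a uniform grid, plus a yaw-rate trajectory (turns)
#' and an axial linear-acceleration envelope.  Canonical postures:
#' standing = all segments vertical (pitch 0); sitting = thighs at pi/2;
#' lying = all segments at pi/2; walking/turning = anti-phase left/right
#' thigh-shank oscillation at the scripted cadence with shank amplitude
#' exceeding thigh amplitude; bend = transient chest pitch to ~pi/4;
#' near-fall = fast chest excursion (peak rate >= 2 rad/s) with recovery
#' within 2 s; fall = excursion ending in sustained lying posture.
#'
#' @param script An `activity_script` from [generate_random_script()].
#' @param rate Grid rate, Hz.
#' @return A `kinematic_profile`: list with `t`, `theta` (n x 5 matrix,
#'   radians), `lin` (n x 5, m/s^2), `yaw` (n, rad/s), `events`, `rate`.
#' @export
script_to_kinematics <- function(script, rate = 100) {
  if (any(script$duration <= 0))
    abort("script durations must be positive",
          class = "nearfallr_validation_error")
  total <- sum(script$duration)
  n <- round(total * rate)
  dt <- 1 / rate
  t <- (seq_len(n) - 1) * dt
  starts <- cumsum(c(0, script$duration))
  events <- tibble(start = starts[-length(starts)], end = starts[-1],
                   label = script$activity)

  pl <- sensor_placements()
  theta <- matrix(0, n, 5, dimnames = list(NULL, pl))
  lin <- matrix(0, n, 5, dimnames = list(NULL, pl))
  yaw <- numeric(n)

  seg_of <- findInterval(t, starts, rightmost.closed = TRUE)
  seg_of[seg_of > nrow(script)] <- nrow(script)
  for (i in seq_len(nrow(script))) {
    idx <- which(seg_of == i)
    if (length(idx) == 0) next
    tau <- t[idx] - starts[i]
    prev <- if (i > 1) as.character(script$activity[i - 1]) else NA_character_
    sk <- segment_kinematics(as.character(script$activity[i]), tau,
                             script$duration[i], script$cadence[i], prev)
    theta[idx, ] <- sk$theta
    lin[idx, ] <- sk$lin
    yaw[idx] <- sk$yaw
  }
  structure(list(t = t, theta = theta, lin = lin, yaw = yaw,
                 events = events, rate = rate),
            class = "kinematic_profile")
}

# central-difference time derivative on a uniform grid
time_derivative <- function(x, dt) {
  n <- length(x)
  if (n < 3) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Render kinematic profiles into a noisy five-sensor IMU session
#'
#' Physics: each sensor's accelerometer reads gravity projected into the
#' (segment-aligned) sensor frame plus the axial linear-acceleration
#' envelope, so `ax = (g + lin) sin(theta)`, `az = (g + lin) cos(theta)`;
#' the pitch gyro reads `d theta/dt` plus a constant per-axis bias; yaw
#' rate appears on `gz`.  White Gaussian noise is added per the noise
#' model.  With zero noise and a static posture the acceleration
#' magnitude is exactly 9.81 m/s^2 at every sample.
#'
#' @param kin A `kinematic_profile` from [script_to_kinematics()].
#' @param noise A [noise_model()].
#' @param subject_id,day_index Session metadata.
#' @param seed Optional integer seed (falls back to `noise$seed`; when
#'   both are `NULL` the current RNG stream is used).
#' @return A `sim_session`: list with `session` (a `session_recording`),
#'   `events` (ground-truth annotations), `tilt_truth` (tibble of true
#'   tilt angles), `gyro_bias` (5 x 3 matrix of true biases).
#' @export
kinematics_to_imu <- function(kin, noise = noise_model(),
                              subject_id = "sim", day_index = 1L,
                              seed = NULL) {
  if (kin$rate <= 0)
    abort("rate must be positive", class = "nearfallr_validation_error")
  seed <- seed %||% noise$seed
  run <- function() {
    pl <- sensor_placements()
    n <- length(kin$t)
    dt <- 1 / kin$rate
    bias <- matrix(runif(15, -noise$bias_range, noise$bias_range), 5, 3,
                   dimnames = list(pl, c("gx", "gy", "gz")))
    traces <- purrr::map(pl, function(p) {
      th <- kin$theta[, p]
      a_r <- GRAVITY + kin$lin[, p]
      imu_trace(tibble(
        t = kin$t,
        ax = a_r * sin(th) + rnorm(n, 0, noise$accel_sd),
        ay = rnorm(n, 0, noise$accel_sd),
        az = a_r * cos(th) + rnorm(n, 0, noise$accel_sd),
        gx = bias[p, "gx"] + rnorm(n, 0, noise$gyro_sd),
        gy = time_derivative(th, dt) + bias[p, "gy"] +
          rnorm(n, 0, noise$gyro_sd),
        gz = kin$yaw + bias[p, "gz"] + rnorm(n, 0, noise$gyro_sd)),
        placement = p, nominal_rate = kin$rate, validate = FALSE)
    })
    names(traces) <- pl
    session <- structure(
      list(traces = traces, subject_id = subject_id,
           day_index = as.integer(day_index), rate = kin$rate, t_origin = 0),
      class = "session_recording")
    tilt_truth <- as_tibble(cbind(tibble(t = kin$t),
                                  as.data.frame(kin$theta)))
    structure(list(session = session, events = kin$events,
                   tilt_truth = tilt_truth, gyro_bias = bias),
              class = "sim_session")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a complete labeled home-monitoring session
#'
#' Convenience wrapper: random script, kinematic expansion and IMU
#' rendering under one master seed, so the whole session is reproducible
#' from `seed` alone.
#'
#' @inheritParams generate_random_script
#' @inheritParams kinematics_to_imu
#' @param rate Sampling rate, Hz.
#' @param seed Integer master seed.
#' @return A `sim_session` (see [kinematics_to_imu()]) with the script
#'   attached as `$script`.
#' @export
simulate_session <- function(total_duration = 600,
                             class_mix = default_class_mix(),
                             mean_durations = default_mean_durations(),
                             noise = noise_model(), rate = 100, seed = 1) {
  withr::with_seed(seed, {
    script <- generate_random_script(total_duration, class_mix,
                                     mean_durations, seed = NULL)
    kin <- script_to_kinematics(script, rate = rate)
    sim <- kinematics_to_imu(kin, noise = noise, seed = NULL)
  })
  sim$script <- script
  sim
}
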