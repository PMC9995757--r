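test_that("random scripts follow the posture grammar and hit the target length", {
  # degenerate mix: only walking, no transitions
  s <- generate_random_script(120, class_mix = c(walk = 1), seed = 1)
  expect_true(all(s$activity == "walk"))
  expect_equal(sum(s$duration), 120, tolerance = 1e-9)
  expect_true(all(s$cadence >= 0.8 & s$cadence <= 1.2))

  # fixed seed reproduces the script exactly
  expect_identical(generate_random_script(300, seed = 9),
                   generate_random_script(300, seed = 9))

  # every sit boundary passes through a transfer segment
  s2 <- generate_random_script(
    600, class_mix = c(sit = 0.5, stand = 0.5), seed = 4)
  a <- as.character(s2$activity)
  sits <- which(a == "sit")
  for (i in sits) {
    if (i > 1 && a[i - 1] != "sit")
      expect_equal(a[i - 1], "stand_to_sit")
    if (i < length(a) && a[i + 1] != "sit")
      expect_equal(a[i + 1], "sit_to_stand")
  }
  # transitions respect their duration bounds
  trans <- s2$duration[a %in% c("stand_to_sit", "sit_to_stand")]
  expect_true(all(trans >= 0.5 - 1e-9 & trans <= 5 + 1e-9))

  expect_error(generate_random_script(100, class_mix = c(walk = 0.7)),
               class = "nearfallr_validation_error")
  expect_error(generate_random_script(-5), class = "nearfallr_validation_error")
})

test_that("kinematic postures match their definitions", {
  mk_script <- function(acts, durs, cad = NA_real_) {
    tibble::tibble(activity = factor(acts, levels = activity_classes()),
                   duration = durs, cadence = cad)
  }
  # standing keeps every segment near vertical
  k <- script_to_kinematics(mk_script("stand", 10))
  expect_lt(max(abs(k$theta)), 0.05)

  # near-fall: fast chest excursion, recovery within 2 s of the peak
  k2 <- script_to_kinematics(mk_script(c("near_fall", "stand"), c(2, 3)))
  chest <- k2$theta[, "chest"]
  rate_max <- max(abs(diff(chest))) * k2$rate
  expect_gte(rate_max, 2)
  ipk <- which.max(abs(chest))
  after <- ipk + 2 * k2$rate
  expect_lt(abs(chest[after] - chest[1]), 0.1)
  # chest acceleration transient at least 5 m/s^2 above gravity
  expect_gte(max(k2$lin[, "chest"]), 5)

  # fall ends lying: terminal chest pitch at pi/2
  k3 <- script_to_kinematics(mk_script(c("stand", "fall"), c(3, 2)))
  expect_lt(abs(k3$theta[nrow(k3$theta), "chest"] - pi / 2), 0.1)

  # sit: thighs at pi/2, shanks and chest near vertical
  k4 <- script_to_kinematics(mk_script(c("stand_to_sit", "sit"), c(1.5, 8)))
  mid <- round(nrow(k4$theta) * 0.7)
  expect_lt(abs(k4$theta[mid, "thigh_l"] - pi / 2), 0.05)
  expect_lt(abs(k4$theta[mid, "shank_l"]), 0.05)
  expect_lt(abs(k4$theta[mid, "chest"]), 0.05)
})

test_that("rendered IMU physics: gravity magnitude, gyro consistency, determinism", {
  sim <- simulate_session(300, noise = noise_model(0, 0, 0), seed = 3)
  # in activity classes without linear acceleration the accel magnitude
  # is exactly g at every sample
  chest <- sim$session$traces$chest
  amag <- sqrt(chest$ax^2 + chest$ay^2 + chest$az^2)
  ev <- sim$events
  quiet <- rep(FALSE, nrow(chest))
  for (i in which(ev$label %in% c("stand", "sit"))) {
    quiet[chest$t >= ev$start[i] & chest$t < ev$end[i]] <- TRUE
  }
  expect_true(any(quiet))
  expect_lt(max(abs(amag[quiet] - 9.81)), 1e-9)

  # ground truth labels partition the session exactly
  expect_equal(ev$start[-1], ev$end[-nrow(ev)])
  expect_equal(max(ev$end), sum(sim$script$duration))
  expect_equal(sum(ev$label == "near_fall"),
               sum(sim$script$activity == "near_fall"))

  # fixed seed reproduces the rendered session bitwise
  sim2 <- simulate_session(300, noise = noise_model(0, 0, 0), seed = 3)
  expect_identical(sim$session$traces$shank_r$gy,
                   sim2$session$traces$shank_r$gy)
})

test_that("noise-free gyro integrates back to the analytic tilt trajectory", {
  rate <- 100
  t <- (seq_len(10 * rate) - 1) / rate
  theta <- 0.3 * sin(2 * pi * t)
  pl <- sensor_placements()
  kin <- structure(list(
    t = t,
    theta = matrix(theta, length(t), 5, dimnames = list(NULL, pl)),
    lin = matrix(0, length(t), 5, dimnames = list(NULL, pl)),
    yaw = numeric(length(t)),
    events = tibble::tibble(start = 0, end = 10,
                            label = factor("stand",
                                           levels = activity_classes())),
    rate = rate), class = "kinematic_profile")
  sim <- kinematics_to_imu(kin, noise = noise_model(0, 0, 0), seed = 1)
  gy <- sim$session$traces$chest$gy
  dt <- 1 / rate
  integ <- theta[1] + c(0, cumsum((gy[-1] + gy[-length(gy)]) / 2 * dt))
  expect_lt(max(abs(integ - theta)), 1e-3)
})

test_that("walking traces place their spectral peak at the scripted cadence", {
  sim <- simulate_session(60, class_mix = c(walk = 1),
                          noise = noise_model(0, 0, 0), seed = 21)
  seg <- sim$events[1, ]
  f_scripted <- sim$script$cadence[1]
  tr <- sim$session$traces$shank_l
  inseg <- tr$t >= seg$start + 0.5 & tr$t < seg$end - 0.5
  x <- tr$gy[inseg] - mean(tr$gy[inseg])
  n <- length(x)
  sp <- Mod(fft(x))[2:floor(n / 2)]
  f_peak <- which.max(sp) * sim$session$rate / n
  expect_lt(abs(f_peak - f_scripted), 0.1)
})
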