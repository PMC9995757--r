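# Shared fixtures and independent oracles used across the suite.

# static upright trace: gravity along sensor z, optional pitch theta
make_static_trace <- function(duration = 5, rate = 100, theta = 0,
                              placement = "chest", gyro_bias = 0,
                              accel_sd = 0, gyro_sd = 0) {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  imu_trace(tibble::tibble(
    t = t,
    ax = 9.81 * sin(theta) + rnorm(n, 0, accel_sd),
    ay = rnorm(n, 0, accel_sd),
    az = 9.81 * cos(theta) + rnorm(n, 0, accel_sd),
    gx = rnorm(n, 0, gyro_sd),
    gy = gyro_bias + rnorm(n, 0, gyro_sd),
    gz = rnorm(n, 0, gyro_sd)),
    placement = placement, nominal_rate = rate)
}

# five static traces assembled into a session of the given duration
make_static_session <- function(duration = 10, rate = 100) {
  traces <- lapply(sensor_placements(), function(p)
    make_static_trace(duration + 1 / rate, rate, placement = p))
  names(traces) <- sensor_placements()
  assemble_session(traces, rate = rate)
}

# sinusoidal-tilt chest trace with known gyro bias (tilt benchmark input)
make_sinusoid_trace <- function(duration = 60, rate = 100, amp = 0.3,
                                freq = 1, bias = 0.05,
                                accel_sd = 0.3, gyro_sd = 0.02) {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  theta <- amp * sin(2 * pi * freq * t)
  omega <- amp * 2 * pi * freq * cos(2 * pi * freq * t)
  imu_trace(tibble::tibble(
    t = t,
    ax = 9.81 * sin(theta) + rnorm(n, 0, accel_sd),
    ay = rnorm(n, 0, accel_sd),
    az = 9.81 * cos(theta) + rnorm(n, 0, accel_sd),
    gx = rnorm(n, 0, gyro_sd),
    gy = omega + bias + rnorm(n, 0, gyro_sd),
    gz = rnorm(n, 0, gyro_sd)),
    placement = "chest", nominal_rate = rate)
}

# brute-force pairwise-concordance AUC (Mann-Whitney, half credit ties)
auc_concordance <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}

# brute-force one-vs-rest counts by explicit enumeration
counts_bruteforce <- function(pred, truth, classes) {
  n <- length(pred)
  out <- NULL
  for (cl in classes) {
    tp <- fp <- tn <- fn <- 0
    for (i in seq_len(n)) {
      if (pred[i] == cl && truth[i] == cl) tp <- tp + 1
      else if (pred[i] == cl) fp <- fp + 1
      else if (truth[i] == cl) fn <- fn + 1
      else tn <- tn + 1
    }
    out <- rbind(out, data.frame(class = cl, tp = tp, fp = fp,
                                 tn = tn, fn = fn))
  }
  out
}

# independent OLS oracle via the pseudoinverse
ols_pinv_oracle <- function(X, y) {
  sv <- svd(X)
  pinv <- sv$v %*% diag(1 / sv$d, length(sv$d)) %*% t(sv$u)
  beta <- drop(pinv %*% y)
  fit <- drop(X %*% beta)
  n <- nrow(X); p <- ncol(X) - 1
  sse <- sum((y - fit)^2)
  sst <- sum((y - mean(y))^2)
  s2 <- sse / (n - p - 1)
  se <- sqrt(diag(solve(crossprod(X))) * s2)
  f <- ((sst - sse) / p) / s2
  list(beta = beta, se = se, sse = sse, f = f)
}

# power-law sampler by inverse CDF: P(D > d) = (d / d_min)^(1 - alpha)
rpowerlaw <- function(n, alpha, d_min) {
  d_min * runif(n)^(-1 / (alpha - 1))
}

# synthetic subject cohort with a known linear fall-frequency model
make_cohort <- function(n = 16,
                        beta = c(0.05, 0.7, 0, -0.0004, -0.015, -0.004),
                        sigma = 0.015, seed = 1) {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      nfall_freq = runif(n, 0, 0.3),
      tot_num_abs = runif(n, 500, 5000),
      sit_freq = runif(n, 10, 60),
      updrs_pull = sample(0:3, n, replace = TRUE),
      alpha_8 = runif(n, 1.5, 4))
    X <- cbind(1, as.matrix(d))
    d$fall_freq <- drop(X %*% beta) + rnorm(n, 0, sigma)
  })
  d
}
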