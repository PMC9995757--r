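# build a tiny two-class window set with a clean mean shift
make_separable_windows <- function(n_per = 10, L = 40, C = 7, gap = 3) {
  withr::with_seed(5, {
    x <- array(rnorm(2 * n_per * L * C, sd = 0.1), c(2 * n_per, L, C))
    x[(n_per + 1):(2 * n_per), , ] <- x[(n_per + 1):(2 * n_per), , ] + gap
  })
  structure(list(
    x = x, t0 = seq_len(2 * n_per) - 1,
    labels = factor(rep(c("stand", "walk"), each = n_per),
                    levels = activity_classes()),
    channels = paste0("ch", seq_len(C)), window_len = L / 100,
    stride = 0.5, rate = 100), class = "window_set")
}

test_that("a linearly separable problem is fit perfectly by logistic regression", {
  w <- make_separable_windows()
  m <- train_classifier(w, "log", seed = 1)
  pr <- predict(m, w)
  expect_equal(mean(as.character(pr$.pred) == as.character(w$labels)), 1)
  probs <- as.matrix(pr[, grep("^\\.prob_", names(pr))])
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-6)
})

test_that("training is seed-deterministic for every classifier kind", {
  w <- make_separable_windows()
  for (k in c("lstm", "log", "svm", "dt")) {
    hy <- if (k == "lstm") list(epochs = 3, decimate = 2) else list()
    m1 <- train_classifier(w, k, hyper = hy, seed = 42)
    m2 <- train_classifier(w, k, hyper = hy, seed = 42)
    p1 <- predict(m1, w)
    p2 <- predict(m2, w)
    expect_identical(p1, p2)
    if (k == "lstm")
      expect_identical(m1$fitted$weights, m2$fitted$weights)
  }
})

test_that("CNN-LSTM analytic gradients match finite differences", {
  withr::with_seed(3, {
    x <- array(rnorm(6 * 24 * 3), c(6, 24, 3))
  })
  y <- c(0L, 1L, 2L, 0L, 1L, 2L)
  w <- c(1, 1.5, 0.5)
  cfg <- list(filters1 = 4, filters2 = 5, kernel = 3, pool = 2, hidden = 6,
              n_class = 3, epochs = 1, batch = 6, lr = 1e-3, clip = 1e9,
              patience = 3, seed = 1)
  wts <- nearfallr:::.cnn_lstm_init(24L, 3L, cfg, 1L)
  lg <- nearfallr:::.cnn_lstm_loss_grad(x, y, w, wts, cfg)
  eps <- 1e-6
  errs <- c()
  withr::with_seed(8, {
    for (nm in names(wts)) {
      for (i in sample(length(wts[[nm]]), min(4, length(wts[[nm]])))) {
        wp <- wts; wp[[nm]][i] <- wp[[nm]][i] + eps
        wm <- wts; wm[[nm]][i] <- wm[[nm]][i] - eps
        num <- (nearfallr:::.cnn_lstm_loss_grad(x, y, w, wp, cfg)$loss -
                nearfallr:::.cnn_lstm_loss_grad(x, y, w, wm, cfg)$loss) /
          (2 * eps)
        errs <- c(errs, abs(num - lg$grad[[nm]][i]) /
                    max(1e-8, abs(num) + abs(lg$grad[[nm]][i])))
      }
    }
  })
  expect_lt(max(errs), 1e-5)
})

test_that("training preconditions are enforced", {
  w <- make_separable_windows(n_per = 4)
  expect_error(train_classifier(w, "log"), "stand",
               class = "nearfallr_data_insufficiency_error")
  w2 <- make_separable_windows()
  w2$labels <- NULL
  expect_error(train_classifier(w2, "dt"),
               class = "nearfallr_validation_error")
})

test_that("prediction breaks probability ties by canonical class order and handles empties", {
  probs <- rbind(c(0.7, 0.3), c(0.5, 0.5), c(0.2, 0.8))
  got <- nearfallr:::prob_argmax(probs, c("stand", "walk"))
  expect_equal(as.character(got), c("stand", "stand", "walk"))

  w <- make_separable_windows()
  m <- train_classifier(w, "dt", seed = 1)
  empty <- w
  empty$x <- w$x[0, , , drop = FALSE]
  empty$t0 <- numeric(0)
  empty$labels <- w$labels[0]
  pr <- predict(m, empty)
  expect_equal(nrow(pr), 0)

  short <- w
  short$x <- w$x[, 1:20, , drop = FALSE]
  expect_error(predict(m, short), class = "nearfallr_validation_error")
})

test_that("label smoothing and event merging follow the median-filter contract", {
  # isolated disagreement between equal neighbors is overruled
  ev <- smooth_and_segment(c("walk", "stand", "walk"), stride = 1)
  expect_equal(as.character(ev$label), "walk")
  expect_equal(ev$end - ev$start, 3)

  # runs merge into one event spanning n * stride
  ev2 <- smooth_and_segment(rep("walk", 20), stride = 1)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$end - ev2$start, 20)

  # a single near-fall window between walk runs is protected
  ev3 <- smooth_and_segment(c(rep("walk", 5), "near_fall", rep("walk", 5)),
                            stride = 0.5)
  expect_true("near_fall" %in% ev3$label)

  # short unprotected events are absorbed into the longer neighbor
  ev4 <- smooth_and_segment(c(rep("walk", 10), "sit", rep("stand", 4)),
                            stride = 1, min_event_len = 2)
  expect_equal(as.character(ev4$label), c("walk", "stand"))
  expect_equal(ev4$end[1], 11)  # absorbed into walk (the longer neighbor)
})

test_that("event streams from smoothing partition the windowed span", {
  withr::with_seed(10, {
    labs <- sample(activity_classes(), 60, replace = TRUE)
  })
  ev <- smooth_and_segment(labs, stride = 0.5, min_event_len = 1)
  expect_equal(ev$start[1], 0)
  expect_equal(max(ev$end), 30)
  if (nrow(ev) > 1) expect_equal(ev$start[-1], ev$end[-nrow(ev)])
})

test_that("near-fall AUC ordering across classifiers holds on most seeds", {
  # enriched near-fall mix so the positive class has real support
  mix <- c(stand = 0.15, walk = 0.25, turn = 0.12, bend = 0.18,
           near_fall = 0.30)
  res <- sapply(1:5, function(s) {
    sim <- simulate_session(1500, class_mix = mix, seed = 300 + s)
    w <- window_session(sim$session, estimate_tilt(sim$session), sim$events)
    n <- n_windows(w)
    idx <- withr::with_seed(s, sample(n))
    tr <- subset_idx <- idx[seq_len(floor(0.7 * n))]
    te <- idx[(floor(0.7 * n) + 1):n]
    wtr <- nearfallr:::subset_windows(w, tr)
    wte <- nearfallr:::subset_windows(w, te)
    auc_of <- function(kind, hy = list()) {
      m <- train_classifier(wtr, kind, hyper = hy, seed = s)
      pr <- predict(m, wte)
      roc_curve_auc(pr$.prob_near_fall, wte$labels == "near_fall")$auc
    }
    c(lstm = auc_of("lstm", list(epochs = 12)),
      log = auc_of("log"), svm = auc_of("svm"), dt = auc_of("dt"),
      n_nf = sum(w$labels == "near_fall"))
  })
  expect_true(all(res["n_nf", ] >= 200))
  ok <- res["lstm", ] >= res["dt", ] - 1e-9 &
    res["dt", ] >= pmin(res["log", ], res["svm", ]) - 1e-9
  expect_gte(sum(ok), 3)
})

test_that("end-to-end prediction pipeline is reproducible from the seeds", {
  sim <- simulate_session(300, seed = 77)
  w <- window_session(sim$session, estimate_tilt(sim$session), sim$events)
  m1 <- train_classifier(w, "lstm", hyper = list(epochs = 2), seed = 5)
  m2 <- train_classifier(w, "lstm", hyper = list(epochs = 2), seed = 5)
  expect_identical(predict(m1, w), predict(m2, w))
})
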