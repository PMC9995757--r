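#' Default CNN-LSTM hyperparameters
#'
#' Two 1-D convolution blocks over time (16 and 32 filters, kernel 5,
#' max-pool 2) feed an LSTM whose final hidden state drives a dense
#' softmax layer.  Windows are decimated from the session rate by block
#' averaging (`decimate`) before the network; tilt dynamics of daily
#' activities live well below the resulting Nyquist.  Training uses
#' Adam on class-weighted cross-entropy with early stopping on a
#' stratified validation split.
#'
#' @return Named list of hyperparameters.
#' @export
lstm_hyper <- function() {
  list(filters1 = 16, filters2 = 32, kernel = 5, pool = 2, hidden = 64,
       epochs = 30, batch = 64, lr = 2e-3, clip = 5, patience = 6,
       val_frac = 0.2, decimate = 4, class_weights = TRUE)
}

# block-average decimation of a window array (n, L, C) -> (n, L/f, C)
decimate_windows <- function(x, f) {
  if (f <= 1) return(x)
  d <- dim(x)
  L2 <- floor(d[2] / f)
  x <- x[, seq_len(L2 * f), , drop = FALSE]
  dim(x) <- c(d[1], f, L2, d[3])
  out <- colMeans(aperm(x, c(2, 1, 3, 4)))
  dim(out) <- c(d[1], L2, d[3])
  out
}

# per-channel summary features for the flat baseline classifiers
flatten_features <- function(x, rate) {
  n <- dim(x)[1]; L <- dim(x)[2]; C <- dim(x)[3]
  fs <- rate
  out <- matrix(0, n, 5 * C)
  nm <- character(5 * C)
  half <- max(2, floor(L / 2))
  for (c in seq_len(C)) {
    ch <- x[, , c, drop = TRUE]
    if (n == 1) ch <- matrix(ch, 1, L)
    mu <- rowMeans(ch)
    s2 <- rowMeans(ch^2) - mu^2
    centered <- ch - mu
    sp <- Mod(t(apply(centered, 1, fft)))[, 2:half, drop = FALSE]
    dom <- (apply(sp, 1, which.max)) * fs / L
    out[, (c - 1) * 5 + 1:5] <- cbind(mu, sqrt(pmax(s2, 0)),
                                      apply(ch, 1, min), apply(ch, 1, max),
                                      dom)
    nm[(c - 1) * 5 + 1:5] <- paste0("ch", c, "_",
                                    c("mean", "sd", "min", "max", "domfreq"))
  }
  colnames(out) <- nm
  out
}

check_trainable <- function(labels) {
  if (is.null(labels))
    abort("training windows must be labeled",
          class = "nearfallr_validation_error")
  tab <- table(droplevels(labels))
  if (length(tab) < 2)
    abort("need at least 2 classes to train a classifier",
          class = "nearfallr_validation_error")
  small <- names(tab)[tab < 5]
  if (length(small) > 0)
    abort(paste0("too few training windows (< 5) for class(es): ",
                 paste(small, collapse = ", ")),
          class = "nearfallr_data_insufficiency_error")
  names(tab)
}

#' Train an activity classifier
#'
#' `kind = "lstm"` trains the CNN-LSTM sequence classifier directly on
#' the windowed channel sequences.  The flat baselines (`"log"`
#' multinomial logistic regression, `"svm"` radial-kernel support
#' vector machine, `"dt"` decision tree) see each window summarized as
#' per-channel mean, sd, min, max and dominant frequency.  Training is
#' deterministic for a fixed seed.
#'
#' @param windows A labeled `window_set` from [window_session()].
#' @param kind One of `"lstm"`, `"log"`, `"svm"`, `"dt"`.
#' @param hyper Named list overriding [lstm_hyper()] entries (LSTM) or
#'   baseline settings (`cost`, `cp`, ...).
#' @param seed Integer seed controlling initialization, shuffling and
#'   the validation split.
#' @return A fitted model of class `nearfall_model`.
#' @export
train_classifier <- function(windows, kind = c("lstm", "log", "svm", "dt"),
                             hyper = list(), seed = 1) {
  kind <- match.arg(kind)
  present <- check_trainable(windows$labels)
  classes <- intersect(activity_classes(), present)
  y <- factor(as.character(windows$labels), levels = classes)

  hp <- lstm_hyper()
  hp[names(hyper)] <- hyper

  if (kind == "lstm") {
    x <- decimate_windows(windows$x, hp$decimate)
    ctr <- apply(x, 3, mean)
    scl <- apply(x, 3, sd)
    scl[scl < 1e-8] <- 1
    for (c in seq_along(ctr)) x[, , c] <- (x[, , c] - ctr[c]) / scl[c]

    yi <- as.integer(y) - 1L
    n <- length(yi)
    val_idx <- withr::with_seed(seed, {
      unlist(lapply(split(seq_len(n), y), function(ix) {
        nv <- floor(length(ix) * hp$val_frac)
        if (nv >= 1 && length(ix) - nv >= 1) sample(ix, nv) else integer(0)
      }), use.names = FALSE)
    })
    tr_idx <- setdiff(seq_len(n), val_idx)

    k <- length(classes)
    w <- if (isTRUE(hp$class_weights)) {
      cnt <- as.numeric(table(y[tr_idx]))
      wt <- n / (k * pmax(cnt, 1))
      wt / mean(wt)
    } else rep(1, k)

    cfg <- list(filters1 = hp$filters1, filters2 = hp$filters2,
                kernel = hp$kernel, pool = hp$pool, hidden = hp$hidden,
                n_class = k, epochs = hp$epochs, batch = hp$batch,
                lr = hp$lr, clip = hp$clip, patience = hp$patience,
                seed = seed)
    fit <- .cnn_lstm_train(
      x[tr_idx, , , drop = FALSE], yi[tr_idx],
      x[val_idx, , , drop = FALSE], yi[val_idx],
      w, cfg)
    fitted <- list(weights = fit$weights, cfg = cfg,
                   center = ctr, scale = scl,
                   history = list(train = fit$train_loss,
                                  val = fit$val_loss,
                                  best_epoch = fit$best_epoch))
  } else {
    xf <- flatten_features(decimate_windows(windows$x, hp$decimate),
                           windows$rate / hp$decimate)
    ctr <- colMeans(xf)
    scl <- apply(xf, 2, sd)
    scl[scl < 1e-8] <- 1
    xs <- scale(xf, center = ctr, scale = scl)
    df <- as.data.frame(xs)
    df$.label <- y
    fit0 <- withr::with_seed(seed, switch(kind,
      log = nnet::multinom(.label ~ ., data = df, trace = FALSE,
                           maxit = 300, MaxNWts = 5000),
      svm = e1071::svm(.label ~ ., data = df, probability = TRUE,
                       kernel = "radial", cost = hp$cost %||% 10),
      dt = rpart::rpart(.label ~ ., data = df, method = "class",
                        cp = hp$cp %||% 0.001)))
    fitted <- list(fit = fit0, center = ctr, scale = scl)
  }

  structure(list(kind = kind, classes = classes, fitted = fitted,
                 hyper = hp, seed = seed,
                 window_len = windows$window_len, stride = windows$stride,
                 rate = windows$rate, channels = windows$channels),
            class = "nearfall_model")
}

#' @export
print.nearfall_model <- function(x, ...) {
  cat(sprintf("<nearfall_model> kind=%s, %d classes, windows %.2g s @ %g Hz\n",
              x$kind, length(x$classes), x$window_len, x$rate))
  invisible(x)
}

#' Predict activity classes for a window set
#'
#' Returns per-window class probabilities (rows summing to 1) and the
#' argmax label; exact probability ties go to the earlier class in
#' canonical order.
#'
#' @param object A `nearfall_model`.
#' @param windows A `window_set` with the geometry the model was
#'   trained on.
#' @param ... Unused.
#' @return A tibble with `t0`, one probability column `.prob_<class>`
#'   per model class, and `.pred` (factor).
#' @export
predict.nearfall_model <- function(object, windows, ...) {
  if (n_windows(windows) == 0) {
    out <- tibble(t0 = numeric(0))
    for (cl in object$classes) out[[paste0(".prob_", cl)]] <- numeric(0)
    out$.pred <- factor(character(0), levels = object$classes)
    return(out)
  }
  if (dim(windows$x)[2] != round(object$window_len * object$rate) ||
      !identical(windows$channels, object$channels))
    abort("window geometry does not match the fitted model",
          class = "nearfallr_validation_error")

  hp <- object$hyper
  if (object$kind == "lstm") {
    x <- decimate_windows(windows$x, hp$decimate)
    for (c in seq_along(object$fitted$center))
      x[, , c] <- (x[, , c] - object$fitted$center[c]) / object$fitted$scale[c]
    probs <- .cnn_lstm_predict(x, object$fitted$weights, object$fitted$cfg)
  } else {
    xf <- flatten_features(decimate_windows(windows$x, hp$decimate),
                           windows$rate / hp$decimate)
    xs <- scale(xf, center = object$fitted$center,
                scale = object$fitted$scale)
    df <- as.data.frame(xs)
    probs <- switch(object$kind,
      log = {
        p <- predict(object$fitted$fit, newdata = df, type = "probs")
        if (is.null(dim(p))) p <- cbind(1 - p, p)  # 2-class case
        p
      },
      svm = {
        pr <- predict(object$fitted$fit, newdata = df, probability = TRUE)
        attr(pr, "probabilities")
      },
      dt = predict(object$fitted$fit, newdata = df, type = "prob"))
    if (is.null(colnames(probs)) || any(colnames(probs) == ""))
      colnames(probs) <- object$classes
    probs <- probs[, object$classes, drop = FALSE]
  }
  probs <- probs / rowSums(probs)
  pred <- prob_argmax(probs, object$classes)
  out <- tibble(t0 = windows$t0)
  for (i in seq_along(object$classes))
    out[[paste0(".prob_", object$classes[i])]] <- probs[, i]
  out$.pred <- pred
  out
}

# argmax over probability rows; exact ties go to the earlier class in
# canonical order (columns are already canonically ordered)
prob_argmax <- function(probs, classes) {
  factor(classes[apply(probs, 1, which.max)], levels = classes)
}

#' Smooth window labels and merge them into an event stream
#'
#' Applies a width-3 median filter to the per-window label sequence
#' (protected classes -- by default `near_fall` and `fall`, which can
#' legitimately occupy a single window -- are never overwritten), then
#' merges runs of equal labels into events.  Events shorter than
#' `min_event_len` (and not protected) are absorbed into their longer
#' neighbor.  A run of `k` windows at stride `s` spans `k * s` seconds.
#'
#' @param labels Time-ordered per-window labels (factor or character).
#' @param stride Window stride, seconds.
#' @param min_event_len Minimum event length, seconds (default 0 =
#'   keep everything).
#' @param origin Start time of the first window, seconds.
#' @param protected Classes exempt from filtering and the minimum
#'   length.
#' @return Event tibble (`start`, `end`, `label`).
#' @export
smooth_and_segment <- function(labels, stride, min_event_len = 0,
                               origin = 0,
                               protected = c("near_fall", "fall")) {
  lab <- as.character(labels)
  n <- length(lab)
  if (n == 0) return(tibble(start = numeric(0), end = numeric(0),
                            label = as_activity(character(0))))
  if (n >= 3) {
    sm <- lab
    for (k in 2:(n - 1)) {
      if (lab[k] %in% protected) next
      if (lab[k - 1] == lab[k + 1]) sm[k] <- lab[k + 1]
    }
    lab <- sm
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  ev <- tibble(start = origin + (starts - 1) * stride,
               end = origin + ends * stride,
               label = r$values)

  if (min_event_len > 0) {
    repeat {
      dur <- ev$end - ev$start
      short <- which(dur < min_event_len & !(ev$label %in% protected))
      if (length(short) == 0 || nrow(ev) == 1) break
      i <- short[which.min(dur[short])]
      nb <- c(if (i > 1) i - 1, if (i < nrow(ev)) i + 1)
      j <- nb[which.max(dur[nb])]
      ev$label[i] <- ev$label[j]
      # merge adjacent equal labels
      r2 <- rle(ev$label)
      e2 <- cumsum(r2$lengths); s2 <- c(1, head(e2, -1) + 1)
      ev <- tibble(start = ev$start[s2], end = ev$end[e2], label = r2$values)
    }
  }
  ev$label <- as_activity(ev$label)
  ev
}
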