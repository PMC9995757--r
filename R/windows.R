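#' Slice a session into fixed-length classifier windows
#'
#' Builds the classifier's input representation: for every window of
#' `window_len` seconds (advancing by `stride`), the per-step channels
#' are the five estimated segment tilt angles, the chest acceleration
#' magnitude (which makes near-fall transients visible) and the chest
#' yaw rate (turning is a transverse-plane motion and is invisible in
#' sagittal tilt).
#' The number of windows is `floor((T - window_len) / stride) + 1`.
#' When ground-truth annotations are supplied, each window is labeled
#' with the class covering the largest fraction of it (ties broken by
#' canonical class order).
#'
#' @param session A `session_recording`.
#' @param tilt The matching `tilt_series` from [estimate_tilt()].
#' @param annotations Optional event tibble (`start`, `end`, `label`).
#' @param window_len,stride Window length and hop, seconds
#'   (`window_len >= stride > 0`).
#' @return A `window_set`: list with `x` (array `n x len x 7`), `t0`
#'   (window start times), `labels` (factor or `NULL`), `channels`,
#'   `window_len`, `stride`, `rate`.
#' @export
window_session <- function(session, tilt, annotations = NULL,
                           window_len = 2, stride = 0.5) {
  if (!(window_len >= stride && stride > 0))
    abort("need window_len >= stride > 0",
          class = "nearfallr_validation_error")
  rate <- session$rate
  chest <- session$traces$chest
  amag <- sqrt(chest$ax^2 + chest$ay^2 + chest$az^2)
  pl <- sensor_placements()
  feat <- cbind(as.matrix(tilt[, pl]), chest_acc = amag,
                chest_yaw = chest$gz)
  n_samp <- nrow(feat)
  total <- n_samp / rate
  wl <- round(window_len * rate)
  hop <- stride * rate

  n_win <- floor((total - window_len) / stride) + 1
  if (n_win < 1) {
    warn("session shorter than window_len: returning an empty window set")
    n_win <- 0
  }
  x <- array(0, dim = c(n_win, wl, ncol(feat)),
             dimnames = list(NULL, NULL, colnames(feat)))
  t0 <- (seq_len(n_win) - 1) * stride
  for (i in seq_len(n_win)) {
    s <- round((i - 1) * hop) + 1
    x[i, , ] <- feat[s:(s + wl - 1), ]
  }

  labels <- NULL
  if (!is.null(annotations) && n_win > 0) {
    annotations <- validate_events(annotations)
    cls <- activity_classes()
    overlap <- matrix(0, n_win, length(cls), dimnames = list(NULL, cls))
    w_end <- t0 + window_len
    for (j in seq_len(nrow(annotations))) {
      ov <- pmax(0, pmin(w_end, annotations$end[j]) -
                      pmax(t0, annotations$start[j]))
      lab <- as.character(annotations$label[j])
      overlap[, lab] <- overlap[, lab] + ov
    }
    labels <- factor(cls[apply(overlap, 1, which.max)], levels = cls)
  }

  structure(list(x = x, t0 = t0, labels = labels,
                 channels = colnames(feat), window_len = window_len,
                 stride = stride, rate = rate),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %.2g s (stride %.2g s), %d channels%s\n",
              n_windows(x), x$window_len, x$stride, length(x$channels),
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' Number of windows in a window set
#' @param windows A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(windows) dim(windows$x)[1]

# subset a window_set by index
subset_windows <- function(windows, idx) {
  out <- windows
  out$x <- windows$x[idx, , , drop = FALSE]
  out$t0 <- windows$t0[idx]
  if (!is.null(windows$labels)) out$labels <- windows$labels[idx]
  out
}

#' Concatenate window sets with identical geometry
#'
#' Useful for pooling windows from several recording sessions into one
#' training set (e.g. to accumulate enough examples of rare classes
#' such as falls).
#'
#' @param a,b `window_set`s with the same window length, rate and
#'   channels.
#' @return A combined `window_set`.
#' @export
bind_window_sets <- function(a, b) {
  stopifnot(identical(dim(a$x)[-1], dim(b$x)[-1]))
  out <- a
  out$x <- array(c(aperm(a$x, c(2, 3, 1)), aperm(b$x, c(2, 3, 1))),
                 dim = c(dim(a$x)[2], dim(a$x)[3], dim(a$x)[1] + dim(b$x)[1]))
  out$x <- aperm(out$x, c(3, 1, 2))
  dimnames(out$x) <- list(NULL, NULL, a$channels)
  out$t0 <- c(a$t0, b$t0)
  if (!is.null(a$labels) && !is.null(b$labels))
    out$labels <- factor(c(as.character(a$labels), as.character(b$labels)),
                         levels = levels(a$labels))
  out
}
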