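#' Ambulatory bouts from an event stream
#'
#' An ambulatory bout is a maximal union of locomotion events (walking
#' and turning) separated by gaps of at most `merge_gap` seconds.
#'
#' @param events Event tibble (`start`, `end`, `label`).
#' @param merge_gap Maximum within-bout gap, seconds (default 2).
#' @return Tibble of bouts (`start`, `end`, `duration`).
#' @export
ambulatory_bouts <- function(events, merge_gap = 2) {
  events <- validate_events(events)
  amb <- dplyr::filter(events, .data$label %in% ambulatory_classes())
  if (nrow(amb) == 0)
    return(tibble(start = numeric(0), end = numeric(0),
                  duration = numeric(0)))
  amb <- dplyr::arrange(amb, .data$start)
  gap <- c(Inf, amb$start[-1] - amb$end[-nrow(amb)])
  amb$bout_id <- cumsum(gap > merge_gap)
  out <- dplyr::summarise(dplyr::group_by(amb, .data$bout_id),
                          start = min(.data$start), end = max(.data$end),
                          .groups = "drop")
  tibble(start = out$start, end = out$end, duration = out$end - out$start)
}

#' Power-law exponent of bout durations (Hill-type MLE)
#'
#' Continuous maximum-likelihood estimator of the power-law exponent of
#' durations exceeding `d_min`:
#' \deqn{\hat\alpha = 1 + n \big/ \sum_i \ln(d_i / d_{min})}
#' over the `n` qualifying durations.  With fewer than `min_n`
#' qualifying durations the estimate is undefined (`NA`).
#'
#' @param durations Numeric vector of bout durations, seconds.
#' @param d_min Lower cutoff, seconds (default 8: the conventional
#'   "alpha_8" biomarker).
#' @param min_n Minimum number of qualifying durations (default 10).
#' @return The estimate, or `NA_real_` when undefined.
#' @export
alpha_exponent <- function(durations, d_min = 8, min_n = 10) {
  d <- durations[is.finite(durations) & durations > d_min]
  if (length(d) < min_n) return(NA_real_)
  1 + length(d) / sum(log(d / d_min))
}

#' Fraction of monitored time spent in each activity
#'
#' @param events Event tibble (`start`, `end`, `label`).
#' @param total_time Total monitored time, seconds (> 0).
#' @return Tibble (`class`, `fraction`) over all ten classes; fractions
#'   sum to 1 for a fully labeled stream.
#' @export
activity_frequencies <- function(events, total_time) {
  if (!is.numeric(total_time) || total_time <= 0)
    abort("total_time must be positive", class = "nearfallr_validation_error")
  events <- validate_events(events)
  events$dur <- events$end - events$start
  by_class <- dplyr::summarise(dplyr::group_by(events, .data$label,
                                               .drop = FALSE),
                               dur = sum(.data$dur), .groups = "drop")
  tibble(class = as.character(by_class$label),
         fraction = by_class$dur / total_time)
}

#' Peak chest acceleration
#'
#' The strongest perturbation experienced per day, measured as the
#' maximum over samples of `| ||a|| - g |` on the chest accelerometer,
#' averaged across days.
#'
#' @param chest A chest [imu_trace()].
#' @param day_bounds Optional tibble/list of day intervals (`start`,
#'   `end`, seconds); default treats the whole trace as one day.
#' @return Mean of the daily maxima, m/s^2 (`NA` for an empty trace).
#' @export
peak_chest_acceleration <- function(chest, day_bounds = NULL) {
  if (is.null(chest) || nrow(chest) == 0) return(NA_real_)
  dev <- abs(sqrt(chest$ax^2 + chest$ay^2 + chest$az^2) - GRAVITY)
  if (is.null(day_bounds))
    day_bounds <- tibble(start = min(chest$t), end = max(chest$t))
  day_bounds <- as_tibble(day_bounds)
  daily <- purrr::pmap_dbl(day_bounds, function(start, end, ...) {
    inb <- chest$t >= start & chest$t <= end
    if (!any(inb)) NA_real_ else max(dev[inb])
  })
  daily <- daily[!is.na(daily)]
  if (length(daily) == 0) NA_real_ else mean(daily)
}

#' Near-fall count and weekly frequency
#'
#' @param events Event tibble (`start`, `end`, `label`).
#' @param observation_weeks Monitoring duration in weeks (> 0).
#' @return Tibble (`nfall_count`, `nfall_freq` per week).
#' @export
near_fall_metrics <- function(events, observation_weeks) {
  if (!is.numeric(observation_weeks) || observation_weeks <= 0)
    abort("observation_weeks must be positive",
          class = "nearfallr_validation_error")
  events <- validate_events(events)
  count <- sum(events$label == "near_fall")
  tibble(nfall_count = count, nfall_freq = count / observation_weeks)
}

#' Compile the per-subject feature table
#'
#' One row per subject combining home-monitoring biomarkers with
#' clinical covariates and the fall-diary outcome.  A missing component
#' (e.g. no chest trace) yields `NA` in the dependent features, never a
#' silent zero.
#'
#' @param subjects Tibble with one row per subject and columns:
#'   `subject_id`; `events` (list of event tibbles or `NULL`); `chest`
#'   (list of chest [imu_trace()]s or `NULL`); `monitored_weeks`
#'   (duration of home monitoring, weeks); `updrs_pull`, `tot_failures`
#'   (clinical covariates); `diary_falls`, `diary_weeks` (prospective
#'   fall diary).  Optional: `day_bounds` (list), `merge_gap`, `d_min`.
#' @param merge_gap,d_min Passed to [ambulatory_bouts()] /
#'   [alpha_exponent()].
#' @return Tibble with columns `subject_id`, `nfall_count`,
#'   `nfall_freq`, `tot_num_abs`, `sit_freq`, `walk_freq`,
#'   `lie_down_freq`, `peak_acc`, `alpha_8`, `updrs_pull`,
#'   `tot_failures`, `fall_freq`.
#' @export
compile_feature_table <- function(subjects, merge_gap = 2, d_min = 8) {
  subjects <- as_tibble(subjects)
  if (anyDuplicated(subjects$subject_id))
    abort("duplicate subject_id in feature inputs",
          class = "nearfallr_validation_error")
  purrr::pmap_dfr(
    list(seq_len(nrow(subjects))),
    function(i) {
      row <- subjects[i, ]
      ev <- row$events[[1]]
      chest <- if ("chest" %in% names(row)) row$chest[[1]] else NULL
      db <- if ("day_bounds" %in% names(row)) row$day_bounds[[1]] else NULL
      weeks <- row$monitored_weeks

      if (!is.null(ev) && nrow(ev) > 0) {
        ev <- validate_events(ev)
        nf <- near_fall_metrics(ev, weeks)
        bouts <- ambulatory_bouts(ev, merge_gap = merge_gap)
        total_time <- max(ev$end) - min(ev$start)
        fr <- activity_frequencies(ev, total_time)
        frac <- setNames(fr$fraction, fr$class)
        nfall_count <- nf$nfall_count
        nfall_freq <- nf$nfall_freq
        tot_num_abs <- nrow(bouts)
        alpha_8 <- alpha_exponent(bouts$duration, d_min = d_min)
        sit_freq <- frac[["sit"]]
        walk_freq <- frac[["walk"]]
        lie_down_freq <- frac[["lie_down"]]
      } else {
        nfall_count <- NA_integer_; nfall_freq <- NA_real_
        tot_num_abs <- NA_integer_; alpha_8 <- NA_real_
        sit_freq <- NA_real_; walk_freq <- NA_real_
        lie_down_freq <- NA_real_
      }
      tibble(
        subject_id = row$subject_id,
        nfall_count = nfall_count,
        nfall_freq = nfall_freq,
        tot_num_abs = tot_num_abs,
        sit_freq = sit_freq,
        walk_freq = walk_freq,
        lie_down_freq = lie_down_freq,
        peak_acc = peak_chest_acceleration(chest, db),
        alpha_8 = alpha_8,
        updrs_pull = row$updrs_pull %||% NA_real_,
        tot_failures = row$tot_failures %||% NA_real_,
        fall_freq = if (is.na(row$diary_falls) || is.na(row$diary_weeks))
          NA_real_ else row$diary_falls / row$diary_weeks)
    })
}
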