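#' Canonical activity classes
#'
#' The ten daily-living activity classes recognized by the pipeline, in
#' canonical order.  The order matters: probability tie-breaks in
#' [predict.nearfall_model()] and one-vs-rest reports always use it.
#'
#' @return Character vector of the ten class names.
#' @export
#' @examples
#' activity_classes()
activity_classes <- function() {
  c("stand", "walk", "stand_to_sit", "sit", "sit_to_stand",
    "turn", "lie_down", "bend", "near_fall", "fall")
}

#' Sensor placements of the five-IMU array
#'
#' One sensor on the chest, one on each thigh and one on each shank
#' (just above the ankle).
#'
#' @return Character vector of the five placement names.
#' @export
sensor_placements <- function() {
  c("chest", "thigh_l", "thigh_r", "shank_l", "shank_r")
}

as_activity <- function(x, arg = "label") {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), activity_classes())
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown %s value(s): %s; allowed classes are: %s",
      arg, paste(bad, collapse = ", "),
      paste(activity_classes(), collapse = ", ")),
      class = "nearfallr_validation_error")
  }
  factor(x, levels = activity_classes())
}

# classes counted as locomotion when building ambulatory bouts
ambulatory_classes <- function() c("walk", "turn")

# standard gravity used throughout (m/s^2)
GRAVITY <- 9.81
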