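#' Athlete configuration
#'
#' Holds the per-athlete leg length `L` used by the chord step-length model
#' [step_distance()]. The literature is ambiguous about whether `L` means the
#' full lower limb or the shank only; here it is a single neutral length the
#' user calibrates per athlete (a longer `L` scales every step linearly).
#'
#' @param athlete_id Character identifier.
#' @param leg_length Leg length in metres; must lie in (0.2, 1.5).
#' @return An object of class `athlete_config`.
#' @export
athlete_config <- function(athlete_id, leg_length) {
  if (!is.character(athlete_id) || length(athlete_id) != 1L) {
    stop("athlete_id must be a single string")
  }
  leg_length <- as.numeric(leg_length)
  if (length(leg_length) != 1L || !is.finite(leg_length) ||
      leg_length <= 0.2 || leg_length >= 1.5) {
    stop("leg_length must be in (0.2, 1.5) metres")
  }
  structure(list(athlete_id = athlete_id, leg_length = leg_length),
            class = "athlete_config")
}

#' Detector configuration
#'
#' All tunables of the step-detection state machine and the default filter.
#'
#' Defaults follow the published algorithm: TO/IC extrema must exceed 1 rad/s
#' in magnitude, no new step may complete within 250 ms of the previous one,
#' and the signal is conditioned with a 2nd-order 5 Hz Butterworth low-pass.
#' The flight-time window (80-1500 ms between TO and IC) and the 0.1 rad/s
#' confirmation hysteresis are engineering guards: the published workflow
#' requires "flight-time consistency" but states no bounds, and a causal
#' extremum decision needs a retreat margin to be jitter-robust.
#'
#' `event_polarity` encodes the sign convention of the sensor: with
#' `"to_ic_negative"` (default, the usual shank-gyro convention) toe-off and
#' initial contact are negative troughs and mid-swing is the positive peak;
#' `"to_ic_positive"` inverts this. The detector additionally adapts polarity
#' on-line when backward steps are recognised.
#'
#' @param magnitude_threshold Minimum |angular rate| (rad/s) for TO/IC extrema.
#' @param refractory Minimum separation (s) between consecutive detected steps
#'   (IC-to-IC); no step can complete within this window of the previous one.
#' @param flight_time_min,flight_time_max Admissible TO-to-IC interval (s).
#' @param event_polarity `"to_ic_negative"` or `"to_ic_positive"`.
#' @param hysteresis Retreat (rad/s) required to confirm a candidate extremum.
#' @param filter_order Butterworth order (only 2 supported).
#' @param filter_cutoff Low-pass cutoff, Hz.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(magnitude_threshold = 1.0,
                            refractory = 0.250,
                            flight_time_min = 0.080,
                            flight_time_max = 1.500,
                            event_polarity = c("to_ic_negative", "to_ic_positive"),
                            hysteresis = 0.1,
                            filter_order = 2,
                            filter_cutoff = 5.0) {
  event_polarity <- match.arg(event_polarity)
  if (magnitude_threshold <= 0) stop("magnitude_threshold must be > 0")
  if (refractory <= 0) stop("refractory must be > 0")
  if (!(flight_time_min > 0 && flight_time_min < flight_time_max)) {
    stop("need 0 < flight_time_min < flight_time_max")
  }
  if (hysteresis < 0) stop("hysteresis must be >= 0")
  if (filter_order != 2) stop("only filter_order = 2 is supported")
  if (filter_cutoff <= 0) stop("filter_cutoff must be > 0")
  structure(list(
    magnitude_threshold = magnitude_threshold,
    refractory = refractory,
    flight_time_min = flight_time_min,
    flight_time_max = flight_time_max,
    event_polarity = event_polarity,
    hysteresis = hysteresis,
    filter_order = filter_order,
    filter_cutoff = filter_cutoff,
    base_sign = if (event_polarity == "to_ic_negative") -1 else +1
  ), class = "detector_config")
}

config_json_keys <- c(
  "magnitude_threshold", "refractory", "flight_time_min", "flight_time_max",
  "event_polarity", "hysteresis", "filter_order", "filter_cutoff",
  "athlete_id", "leg_length", "time_unit"
)

#' Read a configuration JSON document
#'
#' A single JSON object holding detector thresholds and, optionally, athlete
#' fields (`athlete_id`, `leg_length`) and `time_unit`. Unknown keys are an
#' error: a silently ignored typo in a threshold is dangerous.
#'
#' @param path Path to a JSON file.
#' @return A list with elements `detector` ([detector_config()]), `athlete`
#'   ([athlete_config()] or `NULL`) and `time_unit` (`"s"`/`"ms"`).
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a JSON object")
  unknown <- setdiff(names(raw), config_json_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  det_keys <- intersect(names(raw), names(formals(detector_config)))
  detector <- do.call(detector_config, raw[det_keys])
  athlete <- NULL
  if (!is.null(raw$leg_length)) {
    athlete <- athlete_config(
      athlete_id = if (is.null(raw$athlete_id)) "unknown" else raw$athlete_id,
      leg_length = raw$leg_length
    )
  }
  time_unit <- if (is.null(raw$time_unit)) "s" else match.arg(raw$time_unit, c("s", "ms"))
  list(detector = detector, athlete = athlete, time_unit = time_unit)
}
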