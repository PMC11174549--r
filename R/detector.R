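#' Initialise the detector state machine
#'
#' The detector walks a TO -> MSW -> IC cycle on the filtered pitch-rate
#' stream. Within each phase a candidate extremum is the running best
#' polarity-adjusted sample; it is confirmed once the signal retreats from it
#' by the configured hysteresis, which gives a causal, jitter-robust peak
#' decision. Angular displacement is integrated (left-rectangle, actual time
#' deltas) from the TO extremum onward into separate positive and negative
#' buckets, which are snapshotted at each IC candidate and reset after every
#' emitted step so integration drift can never propagate across steps.
#'
#' After a step is emitted the machine is refractory: candidate tracking for
#' the next TO continues, but no step may *complete* within `refractory`
#' seconds of the previous initial contact, which is what precludes double
#' counting of one physical step.
#'
#' @param config A [detector_config()].
#' @return A `detector_state` list.
#' @export
new_detector_state <- function(config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  structure(list(
    phase = "SEEK_TO",
    base_sign = config$base_sign,
    adapt = 1,                 # +1 normal polarity, -1 after a contrary step
    t_prev = NA_real_, w_prev = NA_real_,
    cand_t = NA_real_, cand_v = -Inf,
    t_to = NA_real_, t_msw = NA_real_,
    th_pos = 0, th_neg = 0,
    snap_pos = NA_real_, snap_neg = NA_real_,
    last_ic = -Inf,
    refractory_until = -Inf,
    n_skipped = 0L
  ), class = "detector_state")
}

#' Current phase label of a detector state
#'
#' Reports `"REFRACTORY"` while the emission ban after the last step is
#' active, otherwise the seek phase.
#'
#' @param state A `detector_state`.
#' @param t Current time, seconds.
#' @return One of `"SEEK_TO"`, `"SEEK_MSW"`, `"SEEK_IC"`, `"REFRACTORY"`.
#' @export
detector_phase <- function(state, t) {
  if (state$phase == "SEEK_TO" && t < state$refractory_until) "REFRACTORY"
  else state$phase
}

#' Reset the displacement integrators
#'
#' Zeroes the positive/negative angular-displacement buckets. Called
#' internally after every emitted step (and whenever a new TO candidate
#' restarts integration), so each step's displacement is independent of all
#' samples before its own TO; constant gyro bias therefore contributes at
#' most `bias * flight_time` per step instead of growing with session length.
#'
#' @param state A `detector_state`.
#' @return The state with `th_pos = th_neg = 0`.
#' @export
reset_integrators <- function(state) {
  state$th_pos <- 0
  state$th_neg <- 0
  state
}

#' Adapt the search polarity after an emitted step
#'
#' When a step is recognised whose displacement sign contradicts the current
#' search polarity (e.g. a backward step while forward peaks are being
#' searched), the signs of the peaks searched for subsequent steps are
#' inverted; the inversion holds until a step agreeing with the inverted
#' polarity, i.e. under the default convention until a new forward step,
#' flips it back.
#'
#' Under event sign `e` (the sign of the TO/IC extrema currently searched)
#' the expected displacement sign is `-e`, since the displacement is
#' dominated by the opposite-sign mid-swing lobe.
#'
#' @param state A `detector_state`.
#' @param emitted_step One-row step data frame (needs a `theta` column).
#' @return Updated state.
#' @export
update_polarity <- function(state, emitted_step) {
  e <- state$base_sign * state$adapt
  theta_sign <- if (emitted_step$theta < 0) -1 else 1
  if (theta_sign != -e) state$adapt <- -state$adapt
  state
}

make_step <- function(t_to, t_msw, t_ic, theta, distance) {
  data.frame(
    t_to = t_to, t_msw = t_msw, t_ic = t_ic,
    theta = theta, distance = distance,
    direction = if (theta < 0) "backward" else "forward",
    stringsAsFactors = FALSE
  )
}

#' Feed one sample through the detector
#'
#' Streaming contract: samples must arrive in strictly increasing time order;
#' at most one step record is returned per call; feeding a whole series
#' sample-by-sample is byte-identical to [detect_steps()].
#'
#' @param state A `detector_state` from [new_detector_state()].
#' @param t Sample time, seconds.
#' @param w Filtered pitch rate, rad/s. Non-finite samples are skipped and
#'   counted in `state$n_skipped`.
#' @param config A [detector_config()].
#' @param leg_length Leg length in metres for the per-step distance; `NA`
#'   yields `NA` distances.
#' @return `list(state = <updated state>, step = <one-row data frame or NULL>)`.
#' @export
process_sample <- function(state, t, w, config, leg_length = NA_real_) {
  s <- state
  if (!is.na(s$t_prev) && t <= s$t_prev) {
    stop("samples must arrive in strictly increasing time order")
  }
  if (!is.finite(w)) {
    s$n_skipped <- s$n_skipped + 1L
    return(list(state = s, step = NULL))
  }
  # integrate the previous interval (left rectangle) into signed buckets
  if (!is.na(s$t_prev)) {
    inc <- s$w_prev * (t - s$t_prev)
    if (inc > 0) s$th_pos <- s$th_pos + inc else s$th_neg <- s$th_neg + inc
  }
  e <- config$base_sign * s$adapt # sign of TO/IC extrema
  hys <- config$hysteresis
  step <- NULL

  repeat {
    if (s$phase == "SEEK_TO") {
      m <- e * w
      # a TO candidate must belong to a fresh excursion: only samples on a
      # rising polarity-adjusted signal may seed/extend it, so the decaying
      # tail of the step just completed can never masquerade as the next TO
      rising <- is.na(s$w_prev) || m > e * s$w_prev
      if (rising && m >= config$magnitude_threshold && m > s$cand_v) {
        s$cand_t <- t
        s$cand_v <- m
        s <- reset_integrators(s) # displacement integrates from the TO extremum
      } else if (is.finite(s$cand_v) && s$cand_v - m >= hys) {
        s$t_to <- s$cand_t
        s$phase <- "SEEK_MSW"
        s$cand_t <- NA_real_
        s$cand_v <- -Inf
      }
      break
    } else if (s$phase == "SEEK_MSW") {
      if (t - s$t_to > config$flight_time_max) {
        # stalled: abort without emitting, rejoin the TO search on this sample
        s$phase <- "SEEK_TO"
        s$cand_t <- NA_real_
        s$cand_v <- -Inf
        s <- reset_integrators(s)
        next
      }
      # MSW is the opposite-sign extremum; no magnitude threshold applies,
      # but a candidate below the hysteresis cannot be distinguished from
      # filter ripple by the retreat rule, so the resolution floor is `hys`
      m <- -e * w
      if (m >= max(hys, .Machine$double.eps) && m > s$cand_v) {
        s$cand_t <- t
        s$cand_v <- m
      } else if (is.finite(s$cand_v) && s$cand_v > 0 && s$cand_v - m >= hys) {
        s$t_msw <- s$cand_t
        s$phase <- "SEEK_IC"
        s$cand_t <- NA_real_
        s$cand_v <- -Inf
      }
      break
    } else { # SEEK_IC
      if (t - s$t_to > config$flight_time_max) {
        s$phase <- "SEEK_TO"
        s$cand_t <- NA_real_
        s$cand_v <- -Inf
        s <- reset_integrators(s)
        next
      }
      m <- e * w
      eligible <- m >= config$magnitude_threshold &&
        (t - s$t_to) >= config$flight_time_min &&
        t >= s$last_ic + config$refractory
      if (eligible && m > s$cand_v) {
        s$cand_t <- t
        s$cand_v <- m
        s$snap_pos <- s$th_pos # displacement as of the IC extremum
        s$snap_neg <- s$th_neg
      } else if (is.finite(s$cand_v) && s$cand_v - m >= hys) {
        theta <- select_displacement(s$snap_pos, s$snap_neg)
        dist <- if (is.na(leg_length)) NA_real_ else step_distance(theta, leg_length)
        step <- make_step(s$t_to, s$t_msw, s$cand_t, theta, dist)
        s$last_ic <- s$cand_t
        s$refractory_until <- s$cand_t + config$refractory
        s <- update_polarity(s, step)
        s$phase <- "SEEK_TO"
        s$cand_t <- NA_real_
        s$cand_v <- -Inf
        s$snap_pos <- NA_real_
        s$snap_neg <- NA_real_
        s <- reset_integrators(s)
      }
      break
    }
  }

  s$t_prev <- t
  s$w_prev <- w
  list(state = s, step = step)
}

#' Detect all steps in a series
#'
#' Batch wrapper over [process_sample()]; output is identical to feeding the
#' samples through one at a time. The series is used as given -- apply
#' [lowpass()] first for the published pipeline.
#'
#' @param series A [gyro_series()] (filtered pitch rate).
#' @param config A [detector_config()].
#' @param athlete Optional [athlete_config()]; enables per-step distances.
#' @param segments Optional data frame with columns `pace`, `start`, `end`
#'   (half-open windows) for per-segment totals.
#' @return A `session_result`: list with `steps` (data frame), `n_steps`,
#'   `total_distance_m`, `per_segment` (or `NULL`), `n_skipped`.
#' @export
detect_steps <- function(series, config = detector_config(), athlete = NULL,
                         segments = NULL) {
  stopifnot(inherits(series, "gyro_series"))
  if (length(series$t) < 2L) stop("series must have length >= 2")
  leg <- if (is.null(athlete)) NA_real_ else athlete$leg_length
  state <- new_detector_state(config)
  tt <- series$t
  ww <- series$w
  rows <- vector("list", 64L)
  nstep <- 0L
  for (i in seq_along(tt)) {
    res <- process_sample(state, tt[i], ww[i], config, leg)
    state <- res$state
    if (!is.null(res$step)) {
      nstep <- nstep + 1L
      if (nstep > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[nstep]] <- res$step
    }
  }
  steps <- if (nstep) do.call(rbind, rows[seq_len(nstep)]) else empty_steps()
  session_result(steps, segments = segments, n_skipped = state$n_skipped)
}

#' Assemble a session result
#'
#' @param steps Step data frame.
#' @param segments Optional segment table (`pace`, `start`, `end`); steps are
#'   assigned to segments by their IC time falling in `[start, end)`.
#' @param n_skipped Count of skipped non-finite samples.
#' @return A `session_result` list.
#' @export
session_result <- function(steps, segments = NULL, n_skipped = 0L) {
  validate_steps(steps)
  per_segment <- NULL
  if (!is.null(segments) && nrow(segments)) {
    per_segment <- segments
    per_segment$n_steps <- vapply(seq_len(nrow(segments)), function(i) {
      sum(steps$t_ic >= segments$start[i] & steps$t_ic < segments$end[i])
    }, integer(1))
    per_segment$distance_m <- vapply(seq_len(nrow(segments)), function(i) {
      sel <- steps$t_ic >= segments$start[i] & steps$t_ic < segments$end[i]
      sum(steps$distance[sel])
    }, numeric(1))
  }
  structure(list(
    steps = steps,
    n_steps = nrow(steps),
    total_distance_m = if (nrow(steps)) sum(steps$distance) else 0,
    per_segment = per_segment,
    n_skipped = n_skipped
  ), class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %d steps, %.1f m total\n",
              x$n_steps,
              if (is.na(x$total_distance_m)) NA_real_ else x$total_distance_m))
  if (!is.null(x$per_segment)) {
    cat("  per segment:\n")
    print(x$per_segment, row.names = FALSE)
  }
  if (x$n_skipped > 0L) cat("  skipped samples:", x$n_skipped, "\n")
  invisible(x)
}
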