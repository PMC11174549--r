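# Synthetic shank pitch-rate sessions with exact ground truth.
#
# Waveform family: each gait cycle is three adjacent raised-cosine lobes --
# an event-polarity trough (TO), an opposite-sign mid-swing lobe, and a
# second trough (IC) -- followed by a quiet stance interval completing the
# cycle period 1/cadence. Lobe areas are solved analytically: the mid-swing
# lobe area equals the target step angle theta (a raised cosine of amplitude
# A and width W has area A*W/2, so W = 2*theta/A), which is exactly the
# quantity the detector's displacement-selection rule measures between TO
# and IC. Raised cosines are smooth and essentially band-limited to ~2/W Hz,
# so at the default paces the 5 Hz conditioning filter passes the mid-swing
# lobe nearly intact.

#' Default pace profiles
#'
#' One profile per circuit pace. Cadences and step angles follow the
#' simulator's stated world (walking 1.8 steps/s at 0.55 rad up to sprinting
#' 3.8 steps/s at 0.85 rad); amplitudes are chosen to match field shank-gyro
#' magnitudes (mid-swing peaks of ~4 rad/s walking to ~13 rad/s sprinting,
#' event troughs of 2-6 rad/s, always above the 1 rad/s detection threshold
#' even after 5 Hz filtering). Run-CoD carries per-step angle jitter and ball
#' dribbling per-step amplitude jitter, emulating irregular gait; noise_sd is
#' additive white measurement noise on the rate signal.
#'
#' @return Named list of `pace_profile` lists with fields `pace`, `cadence`
#'   (steps/s), `theta_target` (rad), `msw_amp`, `trough_amp` (rad/s),
#'   `trough_width` (s), `noise_sd` (rad/s), `direction`, `theta_jitter`,
#'   `amp_jitter` (relative half-ranges).
#' @export
default_pace_profiles <- function() {
  mk <- function(pace, cadence, theta, msw_amp, trough_amp, trough_width,
                 noise_sd, direction = "forward",
                 theta_jitter = 0, amp_jitter = 0, gap1 = 0, gap2 = 0) {
    p <- list(
      pace = pace, cadence = cadence, theta_target = theta,
      msw_amp = msw_amp, trough_amp = trough_amp,
      trough_width = trough_width, noise_sd = noise_sd,
      direction = direction, theta_jitter = theta_jitter,
      amp_jitter = amp_jitter, gap1 = gap1, gap2 = gap2
    )
    class(p) <- "pace_profile"
    validate_profile(p)
    p
  }
  list(
    walking        = mk("walking",        1.8, 0.55,  4.0, 2.0, 0.10, 0.05),
    jogging        = mk("jogging",        2.6, 0.65,  6.0, 4.5, 0.04, 0.08,
                        gap1 = 0.015, gap2 = 0.015),
    sprinting      = mk("sprinting",      3.8, 0.85, 15.0, 6.0, 0.04, 0.15,
                        gap2 = 0.02),
    run_CoD        = mk("run_CoD",        3.0, 0.70, 10.0, 4.5, 0.04, 0.12,
                        theta_jitter = 0.15, gap1 = 0.03, gap2 = 0.03),
    ball_dribbling = mk("ball_dribbling", 3.2, 0.45, 10.0, 6.0, 0.04, 0.12,
                        amp_jitter = 0.20, gap1 = 0.05, gap2 = 0.05),
    backward       = mk("backward",       1.6, 0.50,  3.5, 2.0, 0.10, 0.05,
                        direction = "backward")
  )
}

validate_profile <- function(p, magnitude_threshold = 1, refractory = 0.25) {
  stopifnot(p$cadence > 0, p$theta_target > 0, p$msw_amp > 0,
            p$trough_width > 0, p$noise_sd >= 0)
  if (p$trough_amp <= magnitude_threshold) {
    stop("infeasible profile: trough amplitude must exceed the ",
         magnitude_threshold, " rad/s magnitude threshold")
  }
  if (p$cadence * refractory >= 1) {
    stop("infeasible profile: cadence * refractory must be < 1 ",
         "(steps must be separable)")
  }
  if (p$trough_amp * (1 - p$amp_jitter) <= magnitude_threshold) {
    stop("infeasible profile: amplitude jitter can push troughs below the ",
         "magnitude threshold")
  }
  period <- 1 / p$cadence
  swing <- 2 * p$trough_width + 2 * p$theta_target / p$msw_amp + p$gap1 + p$gap2
  if (swing >= period) {
    stop("infeasible profile: swing (", round(swing, 3),
         " s) does not fit in the cycle period (", round(period, 3), " s)")
  }
  invisible(p)
}

# raised-cosine lobe: amp * (1 - cos(2*pi*(t-t0)/width)) / 2 on [t0, t0+width)
rc_lobe <- function(t, t0, width, amp) {
  x <- (t - t0) / width
  inside <- x >= 0 & x < 1
  out <- numeric(length(t))
  out[inside] <- amp * 0.5 * (1 - cos(2 * pi * x[inside]))
  out
}

# Cycle geometry: TO trough, optional gap, MSW lobe, optional gap, IC
# trough; event times relative to the cycle start. The gaps give the 5 Hz
# filter room so adjacent lobes do not smear into each other at fast paces.
cycle_geometry <- function(trough_width, msw_width, gap1 = 0, gap2 = 0) {
  list(
    t_to  = trough_width / 2,
    msw_on = trough_width + gap1,
    t_msw = trough_width + gap1 + msw_width / 2,
    ic_on = trough_width + gap1 + msw_width + gap2,
    t_ic  = 1.5 * trough_width + gap1 + msw_width + gap2,
    swing_end = 2 * trough_width + gap1 + msw_width + gap2
  )
}

# Lay down n_steps cycles of a profile starting at t0 on a fixed sample grid.
# Lobe widths are fixed per profile (w_m = 2 * theta_target / msw_amp); the
# per-step jitter scales amplitudes, so the realised step angle is
# theta_target * msw_scale and the cycle geometry never drifts into the
# refractory margin. Returns list(time, w, truth); no RNG in here.
render_step_train <- function(profile, msw_scales, trough_scales, t0,
                              sample_rate, leg_length, tail = 0.5) {
  n <- length(msw_scales)
  period <- 1 / profile$cadence
  w_t <- profile$trough_width
  w_m <- 2 * profile$theta_target / profile$msw_amp
  starts <- t0 + (seq_len(n) - 1) * period
  dt <- 1 / sample_rate
  tt <- seq(t0, t0 + n * period + tail, by = dt)
  sig <- numeric(length(tt))
  dir_sign <- if (profile$direction == "backward") -1 else 1
  g <- cycle_geometry(w_t, w_m, profile$gap1, profile$gap2)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    s0 <- starts[k]
    idx <- which(tt >= s0 & tt < s0 + g$swing_end + dt)
    tk <- tt[idx]
    sig[idx] <- sig[idx] -
      rc_lobe(tk, s0, w_t, profile$trough_amp * trough_scales[k]) +
      rc_lobe(tk, s0 + g$msw_on, w_m, profile$msw_amp * msw_scales[k]) -
      rc_lobe(tk, s0 + g$ic_on, w_t, profile$trough_amp * trough_scales[k])
    theta_k <- profile$theta_target * msw_scales[k]
    truth[[k]] <- data.frame(
      step = k,
      t_to = s0 + g$t_to, t_msw = s0 + g$t_msw, t_ic = s0 + g$t_ic,
      theta = dir_sign * theta_k,
      distance = step_distance(theta_k, leg_length),
      direction = profile$direction,
      stringsAsFactors = FALSE
    )
  }
  list(time = tt, w = dir_sign * sig, truth = do.call(rbind, truth))
}

draw_step_params <- function(profile, n_steps) {
  msw_scales <- rep(1, n_steps)
  trough_scales <- rep(1, n_steps)
  if (profile$theta_jitter > 0) { # irregular step angles (e.g. run-CoD)
    msw_scales <- msw_scales * (1 + stats::runif(n_steps, -profile$theta_jitter,
                                                 profile$theta_jitter))
  }
  if (profile$amp_jitter > 0) {   # whole-cycle amplitude wobble (dribbling)
    s <- 1 + stats::runif(n_steps, -profile$amp_jitter, profile$amp_jitter)
    msw_scales <- msw_scales * s
    trough_scales <- trough_scales * s
  }
  list(msw_scales = msw_scales, trough_scales = trough_scales)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate one synthetic gait cycle
#'
#' One cycle of the profile's waveform with exact ground truth: the
#' displacement-selection rule applied to the noise-free waveform between the
#' TO and IC extrema recovers `theta_target` (to rectangular-integration
#' accuracy), and the ground-truth distance is `step_distance(theta_target,
#' leg_length)` exactly.
#'
#' @param profile A profile from [default_pace_profiles()].
#' @param leg_length Metres.
#' @param sample_rate Hz.
#' @param noise_sd Additive Gaussian noise SD, rad/s; defaults to the
#'   profile's value. Set 0 for a noise-free cycle.
#' @param seed Optional seed for the noise draw.
#' @return List with `series` (a [gyro_series()]) and `truth` (one-row data
#'   frame: event times, signed theta, distance, direction).
#' @export
generate_step_waveform <- function(profile, leg_length = 0.9,
                                   sample_rate = 200,
                                   noise_sd = profile$noise_sd,
                                   seed = NULL) {
  validate_profile(profile)
  with_seed(seed, {
    par <- draw_step_params(profile, 1L)
    tr <- render_step_train(profile, par$msw_scales, par$trough_scales, t0 = 0.5,
                            sample_rate = sample_rate, leg_length = leg_length)
    tt <- seq(0, max(tr$time), by = 1 / sample_rate)
    w <- numeric(length(tt))
    w[tt >= tr$time[1]] <- tr$w
    if (noise_sd > 0) w <- w + stats::rnorm(length(w), 0, noise_sd)
    list(
      series = gyro_series(tt, w, sample_rate_nominal = sample_rate),
      truth = tr$truth
    )
  })
}

#' Generate a labelled synthetic session over a circuit
#'
#' Emulates one data-collection session: three vertical-jump sync spikes,
#' then `laps` passes over the circuit with one step train per segment and
#' quiet rest gaps in between. Per segment, the ground-truth step count is
#' `round(reference_m / step_distance(theta_target, leg_length))`.
#' Reproducible bit-for-bit under a fixed `seed`.
#'
#' @param circuit A circuit data frame ([build_default_circuit()]).
#' @param athlete An [athlete_config()].
#' @param profiles Named profile list; must cover every circuit pace.
#' @param laps Number of circuit laps.
#' @param seed Seed for all randomness (jitter + noise).
#' @param sample_rate Hz.
#' @param noise Logical; `FALSE` silences measurement noise (jitter remains).
#' @param include_jumps Prepend the three sync jump spikes.
#' @param rest Rest gap between segments, seconds.
#' @return A `synthetic_session`: list with `series`, `truth` (per-step table
#'   with `lap`, `pace`, event times, `theta`, `distance`, `direction`),
#'   `segments` (`lap`, `pace`, `reference_m`, `start`, `end`), `athlete`,
#'   `seed`.
#' @export
generate_session <- function(circuit = build_default_circuit(),
                             athlete = athlete_config("sim", 0.9),
                             profiles = default_pace_profiles(),
                             laps = 1, seed = NULL, sample_rate = 200,
                             noise = TRUE, include_jumps = TRUE, rest = 2) {
  stopifnot(is.data.frame(circuit), nrow(circuit) >= 1)
  missing_prof <- setdiff(circuit$pace, names(profiles))
  if (length(missing_prof)) {
    stop("no profile for pace(s): ", paste(missing_prof, collapse = ", "))
  }
  with_seed(seed, {
    dt <- 1 / sample_rate
    L <- athlete$leg_length
    pieces_t <- list()
    pieces_w <- list()
    noise_sd_pieces <- list()
    truth <- list()
    segments <- list()
    cursor <- 0
    push <- function(tt, ww, nsd) {
      i <- length(pieces_t) + 1L
      pieces_t[[i]] <<- tt
      pieces_w[[i]] <<- ww
      noise_sd_pieces[[i]] <<- rep(nsd, length(tt))
      cursor <<- tt[length(tt)] + dt
    }
    if (include_jumps) {
      tt <- seq(0, 4, by = dt)
      ww <- rc_lobe(tt, 0.8, 0.4, 8) + rc_lobe(tt, 1.8, 0.4, 8) +
        rc_lobe(tt, 2.8, 0.4, 8)
      push(tt, ww, 0.02)
    }
    for (lap in seq_len(laps)) {
      for (j in seq_len(nrow(circuit))) {
        pace <- circuit$pace[j]
        prof <- profiles[[pace]]
        n_steps <- max(1L, round(circuit$reference_m[j] /
                                   step_distance(prof$theta_target, L)))
        # rest gap before the segment
        gap_t <- seq(cursor, cursor + rest, by = dt)
        push(gap_t, numeric(length(gap_t)), 0.02)
        par <- draw_step_params(prof, n_steps)
        tr <- render_step_train(prof, par$msw_scales, par$trough_scales, t0 = cursor,
                                sample_rate = sample_rate, leg_length = L)
        seg_start <- cursor - 0.1
        push(tr$time, tr$w, prof$noise_sd)
        seg <- tr$truth
        seg$lap <- lap
        seg$pace <- pace
        truth[[length(truth) + 1L]] <- seg
        segments[[length(segments) + 1L]] <- data.frame(
          lap = lap, pace = pace, reference_m = circuit$reference_m[j],
          n_steps_truth = n_steps,
          start = seg_start, end = cursor + 1.0, stringsAsFactors = FALSE
        )
      }
    }
    tt <- unlist(pieces_t)
    ww <- unlist(pieces_w)
    nsd <- unlist(noise_sd_pieces)
    if (noise) ww <- ww + stats::rnorm(length(ww), 0, nsd)
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    structure(list(
      series = gyro_series(tt, ww, sample_rate_nominal = sample_rate),
      truth = truth,
      segments = do.call(rbind, segments),
      athlete = athlete,
      seed = seed
    ), class = "synthetic_session")
  })
}

#' Generate a single-pace session
#'
#' Convenience wrapper producing `n_steps` ground-truth steps of one profile
#' after a short quiet lead-in (no jumps); used for per-pace closure checks.
#'
#' @inheritParams generate_session
#' @param profile A pace profile.
#' @param n_steps Number of ground-truth steps.
#' @param noise_sd Noise SD override (default: profile value).
#' @return A `synthetic_session` (single segment).
#' @export
generate_profile_session <- function(profile, n_steps,
                                     athlete = athlete_config("sim", 0.9),
                                     seed = NULL, sample_rate = 200,
                                     noise_sd = profile$noise_sd) {
  validate_profile(profile)
  with_seed(seed, {
    par <- draw_step_params(profile, n_steps)
    tr <- render_step_train(profile, par$msw_scales, par$trough_scales, t0 = 1.0,
                            sample_rate = sample_rate,
                            leg_length = athlete$leg_length)
    dt <- 1 / sample_rate
    tt <- seq(0, max(tr$time), by = dt)
    w <- numeric(length(tt))
    w[length(w) - length(tr$w) + seq_along(tr$w)] <- tr$w
    if (noise_sd > 0) w <- w + stats::rnorm(length(w), 0, noise_sd)
    truth <- tr$truth
    truth$lap <- 1L
    truth$pace <- profile$pace
    structure(list(
      series = gyro_series(tt, w, sample_rate_nominal = sample_rate),
      truth = truth,
      segments = data.frame(
        lap = 1L, pace = profile$pace, reference_m = NA_real_,
        n_steps_truth = n_steps, start = 0,
        end = max(tt) + 1, stringsAsFactors = FALSE
      ),
      athlete = athlete, seed = seed
    ), class = "synthetic_session")
  })
}

#' Derive a second-device stream from a session
#'
#' Emulates a second unit worn on the same shank: the base stream scaled by
#' `1 + gain_delta` (inter-unit gain mismatch), delayed by `time_offset`
#' (linear interpolation on the same clock grid) and overlaid with extra
#' white noise. Ground truth is shared with the base session.
#'
#' @param base_session A `synthetic_session`.
#' @param gain_delta Relative gain difference (e.g. 0.02 for +2%).
#' @param extra_noise_sd Additional white-noise SD, rad/s.
#' @param time_offset Delay of the second device, seconds.
#' @param seed Optional seed for the noise draw.
#' @return A `synthetic_session` whose `series` is the second device.
#' @export
generate_two_device_session <- function(base_session, gain_delta = 0.02,
                                        extra_noise_sd = 0.05,
                                        time_offset = 0, seed = NULL) {
  stopifnot(inherits(base_session, "synthetic_session"))
  s <- base_session$series
  with_seed(seed, {
    w2 <- if (time_offset == 0) s$w else {
      stats::approx(s$t, s$w, xout = s$t - time_offset, rule = 1)$y
    }
    w2[is.na(w2)] <- 0
    w2 <- w2 * (1 + gain_delta)
    if (extra_noise_sd > 0) w2 <- w2 + stats::rnorm(length(w2), 0, extra_noise_sd)
    out <- base_session
    out$series <- gyro_series(s$t, w2, sample_rate_nominal = s$sample_rate_nominal)
    out
  })
}
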