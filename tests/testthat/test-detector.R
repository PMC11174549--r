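test_that("quiet streams produce no steps", {
  z <- make_series(function(t) rep(0, length(t)), duration = 5)
  expect_equal(detect_steps(z, cfg_default, ath)$n_steps, 0)
  res <- detect_steps(make_series(function(t) 0.5 * sin(2 * pi * t),
                                  duration = 5), cfg_default, ath)
  expect_equal(res$n_steps, 0) # sub-threshold oscillation
})

test_that("one clean gait cycle yields exactly one ordered step", {
  for (nm in c("walking", "sprinting", "backward")) {
    wf <- generate_step_waveform(profiles[[nm]], leg_length = 0.9,
                                 noise_sd = 0)
    res <- detect_steps(wf$series, cfg_for(profiles[[nm]]), ath)
    expect_equal(res$n_steps, 1)
    st <- res$steps
    expect_lt(st$t_to, st$t_msw)
    expect_lt(st$t_msw, st$t_ic)
    expect_equal(abs(st$theta), abs(wf$truth$theta), tolerance = 0.01)
  }
})

test_that("a second IC trough 100 ms after the first is not double counted", {
  # TO trough, MSW lobe, then two IC-like troughs 100 ms apart: the second
  # falls inside the refractory window of the completed step
  rc <- gyrogait:::rc_lobe
  tt <- seq(0, 3, by = 1 / 200)
  w <- -rc(tt, 0.50, 0.10, 2.0) + rc(tt, 0.60, 0.28, 4.0) -
    rc(tt, 0.88, 0.08, 2.0) - rc(tt, 0.98, 0.08, 2.0)
  res <- detect_steps(gyro_series(tt, w), cfg_default, ath)
  expect_equal(res$n_steps, 1)
})

test_that("streaming and batch processing are byte-identical", {
  ses <- generate_profile_session(profiles$jogging, 15, athlete = ath,
                                  seed = 11) # profile noise included
  f <- lowpass(ses$series)
  batch <- detect_steps(f, cfg_default, ath)
  state <- new_detector_state(cfg_default)
  collected <- list()
  for (i in seq_along(f$t)) {
    out <- process_sample(state, f$t[i], f$w[i], cfg_default, ath$leg_length)
    state <- out$state
    if (!is.null(out$step)) collected[[length(collected) + 1L]] <- out$step
  }
  streamed <- do.call(rbind, collected)
  rownames(streamed) <- rownames(batch$steps) <- NULL
  expect_identical(batch$steps, streamed)
})

test_that("negating the signal and swapping polarity mirrors the detection", {
  ses <- generate_profile_session(profiles$walking, 12, athlete = ath,
                                  seed = 5)
  f <- lowpass(ses$series)
  neg <- gyro_series(f$t, -f$w, sample_rate_nominal = 200)
  a <- detect_steps(f, cfg_default, ath)
  b <- detect_steps(neg, cfg_inverted, ath)
  expect_equal(a$n_steps, b$n_steps)
  expect_identical(a$steps$t_to, b$steps$t_to)
  expect_identical(a$steps$t_ic, b$steps$t_ic)
  expect_identical(a$steps$theta, -b$steps$theta)
  expect_identical(a$steps$distance, b$steps$distance)
})

test_that("emitted steps always satisfy spacing, flight and threshold rules", {
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    ses <- generate_profile_session(p, 40, athlete = ath, seed = 23) # noisy
    f <- lowpass(ses$series)
    res <- detect_steps(f, cfg_for(p), ath)
    st <- res$steps
    expect_gt(nrow(st), 0)
    if (nrow(st) > 1) {
      expect_true(all(diff(st$t_ic) >= cfg_default$refractory - 1e-9))
    }
    flight <- st$t_ic - st$t_to
    expect_true(all(flight >= cfg_default$flight_time_min - 1e-9))
    expect_true(all(flight <= cfg_default$flight_time_max + 1e-9))
    # TO and IC extrema exceeded the magnitude threshold in the signal fed in
    at <- function(times) {
      vapply(times, function(tm) abs(f$w[which.min(abs(f$t - tm))]), numeric(1))
    }
    expect_true(all(at(st$t_to) >= cfg_default$magnitude_threshold))
    expect_true(all(at(st$t_ic) >= cfg_default$magnitude_threshold))
  }
})

test_that("counts stay within 5% under 0.3 rad/s white noise (100 steps)", {
  for (nm in c("walking", "sprinting", "ball_dribbling")) {
    p <- profiles[[nm]]
    ses <- generate_profile_session(p, 100, athlete = ath, seed = 5,
                                    noise_sd = 0.3)
    res <- detect_steps(lowpass(ses$series), cfg_for(p), ath)
    expect_gte(res$n_steps, 95)
    expect_lte(res$n_steps, 105)
  }
})

test_that("polarity adapts on contrary steps and recovers", {
  st <- new_detector_state(cfg_default)
  expect_equal(st$adapt, 1)
  st2 <- update_polarity(st, data.frame(theta = 0.5))  # forward under +1
  expect_equal(st2$adapt, 1)
  st3 <- update_polarity(st, data.frame(theta = -0.5)) # backward under +1
  expect_equal(st3$adapt, -1)
  st4 <- update_polarity(st3, data.frame(theta = 0.5)) # forward under -1
  expect_equal(st4$adapt, 1)
})

test_that("backward walking entered with forward polarity loses exactly the
           transitional step, then tracks backward", {
  ses <- generate_profile_session(profiles$backward, 20, athlete = ath,
                                  seed = 3, noise_sd = 0)
  res <- detect_steps(lowpass(ses$series), cfg_default, ath)
  expect_equal(res$n_steps, 19) # first two true steps merge at the flip
  expect_true(all(res$steps$direction == "backward"))
})

test_that("stream hygiene: NaN samples are skipped, time must increase", {
  ses <- generate_profile_session(profiles$walking, 5, athlete = ath,
                                  seed = 2, noise_sd = 0)
  f <- lowpass(ses$series)
  w <- f$w
  w[c(100, 200, 300)] <- NaN
  res <- detect_steps(gyro_series(f$t, ifelse(is.finite(w), w, 0)), cfg_default, ath)
  # feed NaNs through process_sample directly (gyro_series rejects them)
  state <- new_detector_state(cfg_default)
  state <- process_sample(state, 0.000, 0.1, cfg_default)$state
  state <- process_sample(state, 0.005, NaN, cfg_default)$state
  expect_equal(state$n_skipped, 1L)
  expect_error(process_sample(state, 0.000, 0.1, cfg_default), "increasing")
  expect_equal(res$n_steps, 5)
})

test_that("detector_phase reports the refractory emission ban", {
  st <- new_detector_state(cfg_default)
  st$refractory_until <- 10
  expect_equal(detector_phase(st, 9.9), "REFRACTORY")
  expect_equal(detector_phase(st, 10.1), "SEEK_TO")
  st$phase <- "SEEK_MSW"
  expect_equal(detector_phase(st, 9.9), "SEEK_MSW")
})
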