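# shared fixtures: everything is generated in code at test time

ath <- athlete_config("t01", 0.9)
cfg_default <- detector_config()
cfg_inverted <- detector_config(event_polarity = "to_ic_positive")
profiles <- default_pace_profiles()

# uniform series from a function of time
make_series <- function(f, duration = 10, fs = 200) {
  tt <- seq(0, duration, by = 1 / fs)
  gyro_series(tt, f(tt), sample_rate_nominal = fs)
}

# steady-state amplitude of a (filtered) sinusoid, by regression on the
# quadrature pair over the final stretch of the signal
sine_amplitude <- function(series, freq, settle = 2) {
  keep <- series$t >= settle
  tt <- series$t[keep]
  fit <- stats::lm(series$w[keep] ~ sin(2 * pi * freq * tt) +
                     cos(2 * pi * freq * tt))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# detector config matched to a profile's direction of travel
cfg_for <- function(profile) {
  if (profile$direction == "backward") cfg_inverted else cfg_default
}
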