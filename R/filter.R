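#' Low-pass filter specification
#'
#' @param order Filter order; only 2 is supported (the published pipeline).
#' @param cutoff Cutoff frequency, Hz.
#' @param sample_rate Sampling frequency, Hz. Must satisfy
#'   `0 < cutoff < sample_rate/2`.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(order = 2, cutoff = 5.0, sample_rate = 200) {
  if (order != 2) stop("only order-2 Butterworth is supported")
  if (!(cutoff > 0 && cutoff < sample_rate / 2)) {
    stop("cutoff must satisfy 0 < cutoff < sample_rate/2 (Nyquist)")
  }
  structure(list(order = order, cutoff = cutoff, sample_rate = sample_rate),
            class = "filter_spec")
}

# Order-2 Butterworth low-pass, bilinear transform with frequency prewarping.
# Returns list(b = numerator, a = denominator), a[1] == 1.
butter2_coefficients <- function(cutoff, sample_rate) {
  K <- tan(pi * cutoff / sample_rate)
  Q <- 1 / sqrt(2)
  norm <- 1 / (1 + K / Q + K * K)
  b0 <- K * K * norm
  list(
    b = c(b0, 2 * b0, b0),
    a = c(1, 2 * (K * K - 1) * norm, (1 - K / Q + K * K) * norm)
  )
}

# Direct-form application with steady-state initial conditions at x[1]
# (as if the first sample had been held forever): a constant input passes
# through exactly, and stream starts produce no startup transient.
butter2_apply <- function(x, b, a) {
  n <- length(x)
  if (n == 0L) return(x)
  x0 <- x[1]
  xm1 <- c(x0, x[-n])
  xm2 <- c(x0, x0, if (n > 1L) x[-c(n - 1L, n)] else NULL)[seq_len(n)]
  v <- b[1] * x + b[2] * xm1 + b[3] * xm2
  as.numeric(stats::filter(v, filter = -a[2:3], method = "recursive",
                           init = c(x0, x0)))
}

#' Low-pass a pitch-rate series
#'
#' Causal single-pass 2nd-order Butterworth low-pass, matching a real-time
#' embedded implementation; timestamps are unchanged and output length equals
#' input length. A zero-phase forward-backward variant is available for
#' offline work (`zero_phase = TRUE`); it removes the ~35 ms group delay at
#' gait frequencies at the cost of causality.
#'
#' Filtering assumes the nominal sampling rate; if timestamp jitter exceeds
#' 20% of the nominal interval a warning is raised (integration elsewhere in
#' the pipeline always uses the actual time deltas).
#'
#' @param series A [gyro_series()].
#' @param spec A [filter_spec()]; defaults to order 2, 5 Hz at the series'
#'   nominal rate.
#' @param zero_phase Apply forward-backward (offline) instead of causal.
#' @return A filtered [gyro_series()].
#' @export
lowpass <- function(series, spec = NULL, zero_phase = FALSE) {
  stopifnot(inherits(series, "gyro_series"))
  if (length(series$t) < 2L) stop("series must have length >= 2")
  fs <- series$sample_rate_nominal
  if (is.null(spec)) spec <- filter_spec(2, 5.0, fs)
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= fs / 2) stop("cutoff at or above Nyquist")
  dts <- diff(series$t)
  nominal_dt <- 1 / fs
  if (max(abs(dts - nominal_dt)) > 0.2 * nominal_dt) {
    warning("timestamp jitter exceeds 20% of the nominal interval; ",
            "filter assumes uniform sampling", call. = FALSE)
  }
  co <- butter2_coefficients(spec$cutoff, fs)
  y <- butter2_apply(series$w, co$b, co$a)
  if (zero_phase) y <- rev(butter2_apply(rev(y), co$b, co$a))
  out <- series
  out$w <- y
  out
}

#' One-sided magnitude spectrum
#'
#' Discrete Fourier magnitude spectrum of the pitch-rate signal, used to
#' inspect noise content when choosing the low-pass cutoff. Requires
#' (near-)uniform sampling. The returned `power` column satisfies Parseval's
#' identity: `sum(power) == mean(w^2)` to numerical precision.
#'
#' @param series A [gyro_series()].
#' @param jitter_tol Maximum relative deviation of any sampling interval from
#'   the median before the series is rejected as non-uniform.
#' @return Data frame with columns `frequency` (Hz), `amplitude` (one-sided
#'   amplitude, rad/s) and `power`.
#' @export
magnitude_spectrum <- function(series, jitter_tol = 0.01) {
  stopifnot(inherits(series, "gyro_series"))
  n <- length(series$t)
  if (n < 2L) stop("series must have length >= 2")
  dts <- diff(series$t)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > jitter_tol * dt) {
    stop("non-uniform sampling beyond tolerance; resample first")
  }
  X <- stats::fft(series$w)
  half <- seq_len(floor(n / 2) + 1L) # bins 0 .. floor(n/2)
  mult <- rep(2, length(half))
  mult[1] <- 1
  if (n %% 2L == 0L) mult[length(half)] <- 1 # Nyquist bin is unpaired
  mag <- Mod(X[half]) / n
  data.frame(
    frequency = (half - 1L) / (n * dt),
    amplitude = mag * mult,
    power = mag^2 * mult
  )
}
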