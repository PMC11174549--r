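#' Synchronize two device streams by their vertical-jump spikes
#'
#' Multi-device sessions start with three vertical jumps; the resulting
#' high-magnitude spike clusters are used to time-align the streams. Both
#' rectified streams are low-passed, checked for the presence of `n_jumps`
#' spike clusters inside the search window, and cross-correlated; the returned
#' offset is the delay of `series_b` relative to `series_a` (positive when
#' `b` lags `a`), i.e. shifting `b` earlier by the offset aligns the jumps.
#'
#' The jump detector thresholds the rectified magnitude at its 99th percentile
#' within the window and groups above-threshold samples into clusters
#' separated by more than `cluster_gap` seconds; any monotone detector
#' consistent with the cross-correlation contract would do.
#'
#' @param series_a,series_b [gyro_series()] objects with equal nominal rates.
#' @param n_jumps Number of jump clusters required in each stream (default 3).
#' @param window Search window from the start of each stream, seconds.
#' @param max_lag Largest |offset| searched, seconds.
#' @param cluster_gap Minimum silence between distinct spike clusters, seconds.
#' @return Offset in seconds (sub-sample, by parabolic interpolation of the
#'   cross-correlation peak).
#' @export
synchronize_by_jumps <- function(series_a, series_b, n_jumps = 3,
                                 window = 30, max_lag = 5,
                                 cluster_gap = 0.3) {
  stopifnot(inherits(series_a, "gyro_series"), inherits(series_b, "gyro_series"))
  fs <- series_a$sample_rate_nominal
  if (fs != series_b$sample_rate_nominal) {
    stop("series must share the same nominal sampling rate")
  }
  prep <- function(s) {
    keep <- s$t - s$t[1] <= window
    if (sum(keep) < 2L) stop("series shorter than the jump search window")
    r <- abs(s$w[keep])
    co <- butter2_coefficients(min(10, fs / 4), fs)
    butter2_apply(r, co$b, co$a)
  }
  count_clusters <- function(x) {
    thr <- stats::quantile(x, 0.99, names = FALSE)
    if (thr <= 0) return(0L)
    above <- which(x >= thr)
    if (!length(above)) return(0L)
    sum(c(TRUE, diff(above) > cluster_gap * fs))
  }
  ra <- prep(series_a)
  rb <- prep(series_b)
  if (count_clusters(ra) < n_jumps || count_clusters(rb) < n_jumps) {
    stop("jumps not found: fewer than ", n_jumps,
         " spike clusters in the search window")
  }
  ra <- ra - mean(ra)
  rb <- rb - mean(rb)
  kmax <- min(round(max_lag * fs), min(length(ra), length(rb)) - 2L)
  lags <- -kmax:kmax
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      n <- min(length(rb) - l, length(ra))
      if (n < 2L) return(-Inf)
      sum(ra[1:n] * rb[(1 + l):(l + n)]) / n
    } else {
      n <- min(length(ra) + l, length(rb))
      if (n < 2L) return(-Inf)
      sum(ra[(1 - l):(n - l)] * rb[1:n]) / n
    }
  }, numeric(1))
  i <- which.max(cc)
  lag <- lags[i]
  # parabolic sub-sample refinement of the correlation peak
  frac <- 0
  if (i > 1L && i < length(cc) && is.finite(cc[i - 1]) && is.finite(cc[i + 1])) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (denom < 0) frac <- 0.5 * (cc[i - 1] - cc[i + 1]) / denom
  }
  # b(t) = a(t - tau): content of b lags a by `lag` samples on the index
  # grid; any difference in the streams' time origins adds on top.
  (lag + frac) / fs + (series_b$t[1] - series_a$t[1])
}
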