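#' Construct a shank pitch angular-velocity series
#'
#' The only signal input of the detection pipeline: a time-stamped stream of
#' the shank angular rate about the sagittal-plane pitch axis. Timestamps are
#' seconds, rates are rad/s. Optional three-axis rates (`gx`, `gy`, `gz`) are
#' carried along untouched for completeness.
#'
#' If the median sampling interval deviates from `1/sample_rate_nominal` by
#' more than 20%, a warning record is attached to the object (and an R warning
#' is raised); processing continues using the actual timestamps.
#'
#' @param timestamps Numeric vector, seconds, strictly increasing, finite.
#' @param pitch_rate Numeric vector, rad/s, finite, same length as `timestamps`.
#' @param sample_rate_nominal Nominal sampling frequency in Hz (default 200).
#' @param gx,gy,gz Optional additional axis rates (rad/s).
#' @return An object of class `gyro_series`: a list with elements `t`, `w`,
#'   `sample_rate_nominal`, optional `gx`/`gy`/`gz`, and a character vector
#'   `warnings` of attached warning records.
#' @export
#' @examples
#' gs <- gyro_series(seq(0, 1, by = 0.005), sin(seq(0, 1, by = 0.005) * 2 * pi))
#' gs
gyro_series <- function(timestamps, pitch_rate, sample_rate_nominal = 200,
                        gx = NULL, gy = NULL, gz = NULL) {
  timestamps <- as.numeric(timestamps)
  pitch_rate <- as.numeric(pitch_rate)
  if (length(timestamps) != length(pitch_rate)) {
    stop("timestamps and pitch_rate must have the same length")
  }
  if (length(timestamps) < 1L) stop("empty series")
  if (!all(is.finite(timestamps)) || !all(is.finite(pitch_rate))) {
    stop("timestamps and pitch_rate must be finite")
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (!is.numeric(sample_rate_nominal) || sample_rate_nominal <= 0) {
    stop("sample_rate_nominal must be a positive number")
  }
  warnings <- character(0)
  if (length(timestamps) > 1L) {
    med_dt <- stats::median(diff(timestamps))
    nominal_dt <- 1 / sample_rate_nominal
    if (abs(med_dt - nominal_dt) > 0.2 * nominal_dt) {
      msg <- sprintf(
        "median sampling interval %.6f s deviates >20%% from nominal %.6f s",
        med_dt, nominal_dt
      )
      warnings <- c(warnings, msg)
      warning(msg, call. = FALSE)
    }
  }
  out <- list(
    t = timestamps, w = pitch_rate,
    sample_rate_nominal = sample_rate_nominal,
    gx = gx, gy = gy, gz = gz,
    warnings = warnings
  )
  class(out) <- "gyro_series"
  out
}

#' @export
print.gyro_series <- function(x, ...) {
  cat(sprintf(
    "<gyro_series> %d samples, %.2f s, nominal %g Hz\n",
    length(x$t), diff(range(x$t)), x$sample_rate_nominal
  ))
  cat(sprintf(
    "  pitch rate [rad/s]: min %.3f, max %.3f\n",
    min(x$w), max(x$w)
  ))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' @export
length.gyro_series <- function(x) length(x$t)

#' @export
as.data.frame.gyro_series <- function(x, ...) {
  df <- data.frame(t = x$t, gyro_pitch = x$w)
  for (ax in c("gx", "gy", "gz")) if (!is.null(x[[ax]])) df[[ax]] <- x[[ax]]
  df
}

# Restrict a series to a [start, end) time window (half-open, so segment
# boundaries never double-count samples).
window_gyro <- function(series, start, end) {
  keep <- series$t >= start & series$t < end
  gyro_series(series$t[keep], series$w[keep],
              sample_rate_nominal = series$sample_rate_nominal)
}

#' Read a gyroscope CSV
#'
#' Expected schema: header with columns `t` (time) and `gyro_pitch` (rad/s);
#' optional `gx`, `gy`, `gz`. Rows containing non-finite values in `t` or
#' `gyro_pitch` are dropped and reported (message plus a `dropped_rows`
#' attribute with the original data row numbers).
#'
#' @param path Path to a CSV file.
#' @param sample_rate_nominal Nominal sampling rate, Hz.
#' @param time_unit `"s"` (default) or `"ms"`; device logs sometimes stamp in
#'   milliseconds, converted here on the way in.
#' @return A [gyro_series()] (with attribute `dropped_rows` when rows were
#'   rejected).
#' @export
read_gyro_csv <- function(path, sample_rate_nominal = 200,
                          time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "gyro_pitch")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  tvec <- as.numeric(df$t)
  wvec <- as.numeric(df$gyro_pitch)
  bad <- !is.finite(tvec) | !is.finite(wvec)
  dropped <- which(bad)
  if (length(dropped)) {
    message(
      "dropped ", length(dropped), " non-finite row(s): ",
      paste(dropped, collapse = ", ")
    )
  }
  tvec <- tvec[!bad]
  wvec <- wvec[!bad]
  if (length(tvec) < 2L) stop("fewer than 2 valid rows in ", path)
  if (time_unit == "ms") tvec <- tvec / 1000
  if (any(diff(tvec) <= 0)) stop("timestamps must be strictly increasing")
  extra <- lapply(c("gx", "gy", "gz"), function(ax) {
    if (ax %in% names(df)) as.numeric(df[[ax]])[!bad] else NULL
  })
  out <- gyro_series(tvec, wvec, sample_rate_nominal = sample_rate_nominal,
                     gx = extra[[1]], gy = extra[[2]], gz = extra[[3]])
  attr(out, "dropped_rows") <- dropped
  out
}

#' Write a gyroscope series to CSV
#'
#' Round-trips losslessly with [read_gyro_csv()] to better than 1e-9.
#'
#' @param series A [gyro_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gyro_csv <- function(series, path) {
  stopifnot(inherits(series, "gyro_series"))
  df <- as.data.frame(series)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) format(col, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

step_csv_cols <- c("t_to", "t_msw", "t_ic", "theta_rad", "distance_m", "direction")

# canonical in-memory step table; one row per detected step
empty_steps <- function() {
  data.frame(
    t_to = numeric(0), t_msw = numeric(0), t_ic = numeric(0),
    theta = numeric(0), distance = numeric(0),
    direction = character(0), stringsAsFactors = FALSE
  )
}

validate_steps <- function(steps) {
  stopifnot(is.data.frame(steps))
  need <- c("t_to", "t_msw", "t_ic", "theta", "distance", "direction")
  if (!all(need %in% names(steps))) {
    stop("step table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(steps)) {
    if (any(!(steps$t_to < steps$t_msw & steps$t_msw < steps$t_ic))) {
      stop("step events must satisfy t_TO < t_MSW < t_IC")
    }
    if (any(!steps$direction %in% c("forward", "backward"))) {
      stop("direction must be 'forward' or 'backward'")
    }
  }
  invisible(steps)
}

#' Write detected steps to CSV
#'
#' Schema: `t_to,t_msw,t_ic,theta_rad,distance_m,direction`; one row per step,
#' numeric columns round-trip to 1e-9 via [read_steps_csv()]. An empty step
#' table produces a header-only file.
#'
#' @param steps Step table as returned by [detect_steps()] (`$steps`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_steps_csv <- function(steps, path) {
  validate_steps(steps)
  out <- data.frame(
    t_to = steps$t_to, t_msw = steps$t_msw, t_ic = steps$t_ic,
    theta_rad = steps$theta, distance_m = steps$distance,
    direction = steps$direction, stringsAsFactors = FALSE
  )
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(col) format(col, digits = 17, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a step CSV written by [write_steps_csv()]
#'
#' @param path Path to the CSV.
#' @return A step data frame with columns `t_to`, `t_msw`, `t_ic`, `theta`,
#'   `distance`, `direction`.
#' @export
read_steps_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(direction = "character"))
  missing_cols <- setdiff(step_csv_cols, names(df))
  if (length(missing_cols)) {
    stop("missing step column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    t_to = as.numeric(df$t_to), t_msw = as.numeric(df$t_msw),
    t_ic = as.numeric(df$t_ic), theta = as.numeric(df$theta_rad),
    distance = as.numeric(df$distance_m),
    direction = df$direction, stringsAsFactors = FALSE
  )
  validate_steps(out)
  out
}
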