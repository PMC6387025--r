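## SensorStream: one sensor's irregularly timestamped 3-axis samples from one
## device, plus uniform resampling onto a 100 Hz grid.

#' Create a sensor stream
#'
#' A sensor stream holds the raw, irregularly timestamped 3-axis samples of
#' one sensor on one device. Units follow the sensor: m/s^2 for the
#' accelerometer, rad/s for the gyroscope, orientation angles for the
#' (software) orientation sensor.
#'
#' @param device `"wrist"` or `"ankle"`.
#' @param sensor `"accelerometer"`, `"gyroscope"` or `"orientation"`.
#' @param time Numeric vector of strictly increasing timestamps in seconds.
#' @param values Numeric matrix, `length(time)` rows by 3 columns (axes x, y, z).
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(device, sensor, time, values) {
  device <- match.arg(device, DEVICES)
  sensor <- match.arg(sensor, SENSORS)
  time <- as.numeric(time)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != 3L) {
    stop("sensor_stream values must have exactly 3 axis columns", call. = FALSE)
  }
  if (nrow(values) != length(time)) {
    stop("sensor_stream values and time lengths differ", call. = FALSE)
  }
  if (length(time) >= 2L && any(diff(time) <= 0)) {
    stop(sprintf("timestamps of %s %s stream are not strictly increasing",
                 device, sensor), call. = FALSE)
  }
  if (anyNA(time) || anyNA(values)) {
    stop("sensor_stream contains missing values", call. = FALSE)
  }
  colnames(values) <- AXES
  structure(list(device = device, sensor = sensor,
                 time = time, values = values),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s %s: %d samples, t in [%.3f, %.3f] s\n",
              x$device, x$sensor, length(x$time),
              if (length(x$time)) min(x$time) else NA,
              if (length(x$time)) max(x$time) else NA))
  invisible(x)
}

stream_key <- function(stream) paste(stream$device, stream$sensor, sep = "_")

#' Resample an irregular stream onto a uniform grid
#'
#' Smartwatch sensors deliver samples at irregular intervals (approximately
#' 100 Hz). Each axis is linearly interpolated between neighbouring raw
#' samples and evaluated on a uniform grid. No extrapolation is performed:
#' the grid must lie inside the stream's time coverage.
#'
#' @param stream A [sensor_stream()].
#' @param rate Sampling rate in Hz (default 100).
#' @param grid Numeric length-2 vector `c(t_start, t_end)` in seconds. The
#'   output grid is `seq(t_start, by = 1/rate)` up to `t_end`.
#' @return List with `time` (uniform grid) and `values` (matrix, 3 columns).
#' @export
resample_stream <- function(stream, rate = 100, grid) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (length(stream$time) < 2L) {
    stop("resampling needs at least 2 raw samples", call. = FALSE)
  }
  if (!is.numeric(grid) || length(grid) != 2L || grid[2] < grid[1]) {
    stop("grid must be c(t_start, t_end) with t_end >= t_start", call. = FALSE)
  }
  eps <- 1e-9  # tolerate float roundoff at the coverage edges
  if (grid[1] < stream$time[1] - eps ||
      grid[2] > stream$time[length(stream$time)] + eps) {
    stop(sprintf("grid [%g, %g] outside coverage [%g, %g] of %s %s stream",
                 grid[1], grid[2], stream$time[1],
                 stream$time[length(stream$time)],
                 stream$device, stream$sensor), call. = FALSE)
  }
  tg <- seq(grid[1], grid[2] + eps, by = 1 / rate)
  tg <- tg[tg <= grid[2] + eps]
  out <- vapply(1:3, function(a) {
    stats::approx(stream$time, stream$values[, a], xout = tg, rule = 1)$y
  }, numeric(length(tg)))
  out <- matrix(out, ncol = 3, dimnames = list(NULL, AXES))
  ## grid edges may exceed raw coverage by < eps; clamp to nearest sample
  for (a in 1:3) {
    if (anyNA(out[, a])) {
      nas <- which(is.na(out[, a]))
      out[nas, a] <- stream$values[
        pmax(1, pmin(length(stream$time),
                     findInterval(tg[nas], stream$time) + 1L)), a]
    }
  }
  list(time = tg, values = out)
}
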