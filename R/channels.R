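## ChannelMatrix: uniformly resampled signals stacked into N x (3*S) channels
## in canonical order. With both watches and all three sensors this is the
## 18-input representation the networks consume.

#' Construct a channel matrix
#'
#' Usually produced by [assemble_channels()]; exposed for synthetic pipelines
#' and tests.
#'
#' @param data Numeric matrix, N samples by `3*S` channels.
#' @param rate Sampling rate in Hz.
#' @param t0 Time (seconds) of the first row.
#' @param channel_order data.frame with columns `device`, `sensor`, `axis`,
#'   one row per column of `data`.
#' @return An object of class `channel_matrix`.
#' @export
channel_matrix <- function(data, rate, t0, channel_order) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) %% 3L != 0L) {
    stop("channel count must be divisible by 3", call. = FALSE)
  }
  if (nrow(channel_order) != ncol(data)) {
    stop("channel_order length must equal channel count", call. = FALSE)
  }
  structure(list(data = data, rate = rate, t0 = t0,
                 channel_order = channel_order),
            class = "channel_matrix")
}

#' @export
print.channel_matrix <- function(x, ...) {
  cat(sprintf("<channel_matrix> %d samples x %d channels @ %g Hz, t0 = %.3f s\n",
              nrow(x$data), ncol(x$data), x$rate, x$t0))
  invisible(x)
}

#' Common resampling grid of selected streams
#'
#' The grid starts at the latest first-timestamp and ends at the earliest
#' last-timestamp across the selected streams, so interpolation never
#' extrapolates.
#'
#' @param session A [wod_session()].
#' @param selection data.frame with columns `device`, `sensor`.
#' @return Numeric `c(t_start, t_end)`.
#' @export
common_grid <- function(session, selection = all_sensor_pairs()) {
  streams <- lapply(seq_len(nrow(selection)), function(i) {
    get_stream(session, selection$device[i], selection$sensor[i])
  })
  lo <- max(vapply(streams, function(s) s$time[1], numeric(1)))
  hi <- min(vapply(streams, function(s) s$time[length(s$time)], numeric(1)))
  if (hi <= lo) stop("selected streams have no common time coverage", call. = FALSE)
  c(lo, hi)
}

#' Resample and stack a session's streams into a channel matrix
#'
#' Each selected stream is resampled at `rate` on a common grid and its three
#' axes stacked column-wise in the fixed canonical order (wrist before ankle;
#' accelerometer, gyroscope, orientation; axes x, y, z) regardless of the
#' order streams appear in the session. Selecting all six (device, sensor)
#' pairs yields 18 channels.
#'
#' @param session A [wod_session()].
#' @param selection data.frame with columns `device`, `sensor`
#'   (default: all six pairs).
#' @param rate Sampling rate in Hz (default 100).
#' @param grid Optional `c(t_start, t_end)`; default [common_grid()].
#' @return A [channel_matrix()] with `3 * nrow(selection)` channels.
#' @export
assemble_channels <- function(session, selection = all_sensor_pairs(),
                              rate = 100, grid = NULL) {
  stopifnot(inherits(session, "wod_session"))
  order_df <- canonical_channel_order(selection)
  if (nrow(order_df) != 3L * nrow(unique(selection[, c("device", "sensor")]))) {
    stop("selection contains unknown (device, sensor) pairs", call. = FALSE)
  }
  pairs <- unique(order_df[, c("device", "sensor")])
  if (is.null(grid)) grid <- common_grid(session, pairs)
  cols <- list(); tg <- NULL
  for (i in seq_len(nrow(pairs))) {
    stream <- get_stream(session, pairs$device[i], pairs$sensor[i])
    rs <- resample_stream(stream, rate = rate, grid = grid)
    tg <- rs$time
    cols[[i]] <- rs$values
  }
  data <- do.call(cbind, cols)
  colnames(data) <- paste(order_df$device,
                          substr(order_df$sensor, 1, 4), order_df$axis,
                          sep = "_")
  channel_matrix(data, rate = rate, t0 = tg[1], channel_order = order_df)
}

#' Slice a channel matrix by time
#'
#' @param matrix A [channel_matrix()].
#' @param from,to Time range in seconds (clamped to coverage).
#' @return A [channel_matrix()] covering the intersection.
#' @export
slice_channels <- function(matrix, from, to) {
  stopifnot(inherits(matrix, "channel_matrix"))
  n <- nrow(matrix$data)
  i0 <- max(1L, 1L + as.integer(ceiling((from - matrix$t0) * matrix$rate - 1e-9)))
  i1 <- min(n, 1L + as.integer(floor((to - matrix$t0) * matrix$rate + 1e-9)))
  if (i1 < i0) stop("empty time slice", call. = FALSE)
  channel_matrix(matrix$data[i0:i1, , drop = FALSE], rate = matrix$rate,
                 t0 = matrix$t0 + (i0 - 1L) / matrix$rate,
                 channel_order = matrix$channel_order)
}
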