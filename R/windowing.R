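## Window extraction and labeling. Recognition uses a single window length
## W = T*100 (default T = 4 s); counting uses the per-exercise window length
## w_i = round(t_min_i * rate), which guarantees one window never fully
## contains two repetition starts.

#' Stride between consecutive windows from the overlap factor
#'
#' Consecutive test windows overlap by a factor `gamma` in `[0, 1)`; the
#' stride in samples is `max(1, round(W * (1 - gamma)))`.
#'
#' @param W Window length in samples.
#' @param gamma Overlap factor, `0 <= gamma < 1`.
#' @return Integer stride in samples.
#' @export
compute_stride <- function(W, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma >= 1) {
    stop("gamma must lie in [0, 1)", call. = FALSE)
  }
  if (W < 1L) stop("W must be >= 1", call. = FALSE)
  max(1L, as.integer(round(W * (1 - gamma))))
}

#' Extract overlapping windows from a channel matrix
#'
#' Windows start at sample offsets `0, stride, 2*stride, ...`; trailing
#' samples shorter than `W` are dropped (no padding). If the matrix holds
#' fewer than `W` samples an empty window set is returned with a warning.
#'
#' @param matrix A [channel_matrix()].
#' @param W Window length in samples.
#' @param stride Stride between window starts in samples.
#' @return Object of class `window_set`: list with `data` (array
#'   `W x channels x n`), `starts` (0-based sample offsets), `W`, `stride`,
#'   `rate`, `t0`.
#' @export
extract_windows <- function(matrix, W, stride) {
  stopifnot(inherits(matrix, "channel_matrix"))
  W <- as.integer(W); stride <- as.integer(stride)
  stopifnot(W >= 1L, stride >= 1L)
  n_samp <- nrow(matrix$data)
  if (n_samp < W) {
    warning(sprintf("matrix has %d samples < window length %d; no windows",
                    n_samp, W), call. = FALSE)
    starts <- integer(0)
  } else {
    n_win <- (n_samp - W) %/% stride + 1L
    starts <- (seq_len(n_win) - 1L) * stride
  }
  C <- ncol(matrix$data)
  data <- array(0, dim = c(W, C, length(starts)))
  for (i in seq_along(starts)) {
    data[, , i] <- matrix$data[(starts[i] + 1L):(starts[i] + W), ]
  }
  structure(list(data = data, starts = starts, W = W, stride = stride,
                 rate = matrix$rate, t0 = matrix$t0),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples x %d channels (stride %d)\n",
              length(x$starts), x$W, dim(x$data)[2], x$stride))
  invisible(x)
}

n_windows <- function(ws) length(ws$starts)

#' Recognition labels for windows
#'
#' Each window takes the label of the set covering the majority (> 50%) of
#' its samples; windows not majority-covered by any set are labeled
#' `"null"`. Ties go to the earlier set.
#'
#' @param windows A `window_set` extracted from a matrix aligned with
#'   `session` (same `t0` and rate).
#' @param session A [wod_session()] providing the set annotations.
#' @return Character vector of labels, one per window.
#' @export
label_recognition_windows <- function(windows, session) {
  stopifnot(inherits(windows, "window_set"), inherits(session, "wod_session"))
  t_lo <- windows$t0 + windows$starts / windows$rate
  t_hi <- t_lo + windows$W / windows$rate
  labels <- rep(null_label(), length(t_lo))
  if (!length(session$sets)) return(labels)
  best <- rep(0, length(t_lo))
  for (set in session$sets) {           # sets are ordered; ties keep earlier
    ov <- pmax(0, pmin(t_hi, set$end) - pmax(t_lo, set$start))
    take <- ov > best & ov > (windows$W / windows$rate) / 2
    labels[take] <- set$label
    best <- pmax(best, ov)
  }
  labels
}

#' Repetition-start labels for counting windows
#'
#' The start of a repetition is the first `floor(w/2)` samples after the
#' vibration. A window is labeled 1 if and only if it entirely contains some
#' start segment `[v, v + floor(w/2))` (half-open, sample units), else 0.
#'
#' @param windows A `window_set` whose window length equals the counting
#'   window `w` of the set's exercise.
#' @param set An [exercise_set()] carrying the vibration times.
#' @param cfg An [exercise_config()].
#' @return Integer vector of 0/1 labels, one per window.
#' @export
label_counting_windows <- function(windows, set, cfg) {
  stopifnot(inherits(windows, "window_set"), inherits(set, "exercise_set"),
            inherits(cfg, "exercise_config"))
  w <- cfg$w[set$label]
  if (is.na(w)) stop("no counting window configured for ", set$label, call. = FALSE)
  if (windows$W != w) {
    stop(sprintf("window length %d does not match counting window %d for %s",
                 windows$W, w, set$label), call. = FALSE)
  }
  half <- w %/% 2L
  v_samp <- as.integer(round((set$vibrations - windows$t0) * windows$rate))
  bits <- integer(n_windows(windows))
  for (v in v_samp) {
    hit <- windows$starts <= v & (v + half) <= (windows$starts + w)
    bits[hit] <- 1L
  }
  bits
}

#' Sample a training batch uniformly with replacement
#'
#' Training batches are drawn i.i.d. uniformly (with replacement) from the
#' labeled window pool.
#'
#' @param n_pool Pool size.
#' @param batch_size Batch size (default 30).
#' @return Integer vector of `batch_size` pool indices.
#' @export
sample_training_batch <- function(n_pool, batch_size = 30) {
  if (n_pool < 1L) stop("empty training pool", call. = FALSE)
  sample.int(n_pool, size = batch_size, replace = TRUE)
}
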