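## Repetition counting from the binary start-detection sequence: run-length
## encoding, mode-based smoothing of spurious short detections, and the final
## count of 1-runs.

#' Run-length summary of a binary sequence
#'
#' Encodes the sequence into maximal runs and computes the repetition modes:
#' `M1`, the most frequent 1-run length, and `M0`, the most frequent 0-run
#' length. When two lengths are equally frequent the larger one is taken
#' (conservative: it favors confirming runs). A mode is `NA` when no run of
#' that value exists.
#'
#' @param bits Integer/logical vector of 0s and 1s, one per window position.
#' @return List with `runs` (data.frame `value`, `start` 0-based, `length`),
#'   `M1` and `M0`.
#' @export
run_lengths <- function(bits) {
  bits <- as.integer(bits)
  if (!length(bits)) stop("empty binary sequence", call. = FALSE)
  if (!all(bits %in% 0:1)) stop("sequence must be binary", call. = FALSE)
  r <- rle(bits)
  ends <- cumsum(r$lengths)
  runs <- data.frame(value = r$values,
                     start = ends - r$lengths,
                     length = r$lengths)
  mode_len <- function(lens) {
    if (!length(lens)) return(NA_integer_)
    tab <- table(lens)
    best <- as.integer(names(tab)[tab == max(tab)])
    max(best)                               # ties -> larger length
  }
  list(runs = runs,
       M1 = mode_len(runs$length[runs$value == 1L]),
       M0 = mode_len(runs$length[runs$value == 0L]))
}

#' Smooth a binary repetition-start sequence
#'
#' 1-runs of length at least `M1/2` are confirmed repetition starts; shorter
#' 1-runs are removal candidates. A candidate is realistic — and kept — only
#' if no confirmed repetition starts within `M0/2` positions before or after
#' it (start-to-start distance, strictly closer than `M0/2` counts as a
#' conflict). Unrealistic candidates are zeroed; everything else is
#' unchanged, so the output 1-set is a subset of the input 1-set.
#'
#' Candidates are checked against the confirmed set only, in a single pass.
#' If the sequence has no 1-run it is returned unchanged with a warning; if
#' no run reaches `M1/2` (all candidates), the longest run is taken as
#' confirmed and a warning is raised.
#'
#' @param bits Integer/logical vector of 0s and 1s.
#' @return Integer vector of the same length.
#' @export
smooth_binary <- function(bits) {
  bits <- as.integer(bits)
  rl <- run_lengths(bits)
  ones <- rl$runs[rl$runs$value == 1L, , drop = FALSE]
  if (!nrow(ones)) {
    warning("no 1-runs in binary sequence; returned unchanged", call. = FALSE)
    return(bits)
  }
  confirmed <- ones$length >= rl$M1 / 2
  if (!any(confirmed)) {
    warning("no confirmed repetition starts; keeping the longest 1-run",
            call. = FALSE)
    confirmed[which.max(ones$length)] <- TRUE
  }
  cand <- which(!confirmed)
  if (!length(cand) || is.na(rl$M0)) return(bits)
  conf_starts <- ones$start[confirmed]
  for (i in cand) {
    d <- abs(conf_starts - ones$start[i])
    if (any(d < rl$M0 / 2)) {
      bits[(ones$start[i] + 1L):(ones$start[i] + ones$length[i])] <- 0L
    }
  }
  bits
}

#' Count repetitions in a binary start sequence
#'
#' The repetition count is the number of maximal 1-runs after
#' [smooth_binary()].
#'
#' @param bits Integer/logical vector of 0s and 1s.
#' @param smooth Apply [smooth_binary()] first (default `TRUE`).
#' @return Integer repetition count.
#' @export
count_repetitions <- function(bits, smooth = TRUE) {
  bits <- as.integer(bits)
  if (!length(bits) || !any(bits == 1L)) return(0L)
  if (smooth) bits <- smooth_binary(bits)
  r <- rle(bits)
  sum(r$values == 1L)
}

#' Count repetitions in one recognized exercise segment
#'
#' Slides counting windows of the exercise-specific length
#' `w = round(t_min * rate)` over the segment at stride
#' `max(1, round(w / stride_divisor))`, thresholds the per-window start
#' probability of the exercise's counting network, smooths the resulting
#' binary sequence and counts the remaining 1-runs.
#'
#' @param matrix A [channel_matrix()] covering the segment.
#' @param label Exercise code of the segment.
#' @param models Named list of fitted binary [har_cnn()] counting models
#'   (classes `"0"`, `"1"`), one per exercise code.
#' @param cfg An [exercise_config()].
#' @param threshold Probability threshold for a 1 (default 0.5).
#' @param stride_divisor Counting stride is `w / stride_divisor`
#'   (default 20, dense enough that every start segment is fully contained
#'   in at least one window).
#' @return List with `count`, `bits` (smoothed), `raw_bits`, `starts`.
#' @export
count_segment <- function(matrix, label, models, cfg, threshold = 0.5,
                          stride_divisor = 20) {
  stopifnot(inherits(matrix, "channel_matrix"), inherits(cfg, "exercise_config"))
  label <- match_label(label, allow_null = FALSE)
  model <- models[[label]]
  if (is.null(model)) {
    stop("no counting model for exercise ", label, call. = FALSE)
  }
  w <- cfg$w[label]
  if (nrow(matrix$data) < w) {
    warning(sprintf("segment shorter than one counting window for %s; count 0",
                    label), call. = FALSE)
    return(list(count = 0L, bits = integer(), raw_bits = integer(),
                starts = integer()))
  }
  stride <- max(1L, as.integer(round(w / stride_divisor)))
  ws <- extract_windows(matrix, W = w, stride = stride)
  p <- predict(model, ws, type = "prob")[, "1"]
  raw <- as.integer(p >= threshold)
  if (!any(raw == 1L)) {
    return(list(count = 0L, bits = raw, raw_bits = raw, starts = ws$starts))
  }
  bits <- smooth_binary(raw)
  list(count = count_repetitions(bits, smooth = FALSE), bits = bits,
       raw_bits = raw, starts = ws$starts)
}
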