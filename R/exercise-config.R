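## Per-exercise minimum repetition durations. For each exercise the minimum
## duration t_min is the shortest vibration interval observed for it in the
## training data; the counting window length is w = round(t_min * rate).

#' Per-exercise minimum repetition durations
#'
#' @param t_min Named numeric vector (names = exercise codes) of minimum
#'   repetition durations in seconds.
#' @param rate Sampling rate in Hz used to derive window lengths.
#' @return Object of class `exercise_config` with fields `t_min` (seconds)
#'   and `w` (window length in samples, `round(t_min * rate)`).
#' @export
exercise_config <- function(t_min, rate = 100) {
  t_min <- unlist(t_min)
  if (is.null(names(t_min)) || any(!nzchar(names(t_min)))) {
    stop("t_min must be named by exercise code", call. = FALSE)
  }
  bad <- setdiff(names(t_min), exercise_codes())
  if (length(bad)) stop("unknown exercise codes: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(!is.finite(t_min)) || any(t_min <= 0)) {
    stop("t_min values must be positive", call. = FALSE)
  }
  w <- setNames(as.integer(round(t_min * rate)), names(t_min))
  if (any(w < 2L)) stop("counting window w = round(t_min * rate) must be >= 2",
                        call. = FALSE)
  structure(list(t_min = t_min, w = w, rate = rate), class = "exercise_config")
}

#' @export
print.exercise_config <- function(x, ...) {
  cat("<exercise_config> t_min (s):\n")
  print(round(x$t_min, 3))
  invisible(x)
}

#' Estimate minimum repetition durations from annotated sessions
#'
#' For every exercise, scans all constrained sets and takes the shortest
#' vibration interval observed.
#'
#' @param sessions List of [wod_session()] objects with vibration-annotated
#'   sets.
#' @param rate Sampling rate in Hz.
#' @return An [exercise_config()].
#' @export
estimate_exercise_config <- function(sessions, rate = 100) {
  t_min <- numeric()
  for (sess in sessions) {
    for (set in sess$sets) {
      if (set$label == null_label() || length(set$vibrations) < 2L) next
      m <- min(diff(set$vibrations))
      cur <- t_min[set$label]
      if (is.na(cur) || m < cur) t_min[set$label] <- m
    }
  }
  if (!length(t_min)) stop("no vibration-annotated sets found", call. = FALSE)
  exercise_config(t_min, rate = rate)
}
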