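## Session: one participant's annotated recording — ordered exercise sets with
## vibration (repetition-start) annotations plus the raw sensor streams.

#' Create an exercise set annotation
#'
#' One set of one exercise (or a null segment) within a session. During a
#' constrained workout the wrist watch vibrates at the start of each
#' repetition, so `vibrations` holds the repetition-start times and
#' `declared_reps` equals their number. Unconstrained sets carry no
#' vibrations.
#'
#' @param label Exercise code `"E1"`..`"E10"` or `"null"`.
#' @param start,end Set boundaries in seconds, `end > start`.
#' @param vibrations Strictly increasing repetition-start times (seconds)
#'   inside `[start, end]`; may be empty.
#' @param declared_reps Declared repetition count, or `NA` if unknown.
#' @return An object of class `exercise_set`.
#' @export
exercise_set <- function(label, start, end, vibrations = numeric(),
                         declared_reps = NA_integer_) {
  label <- match_label(label)
  start <- as.numeric(start); end <- as.numeric(end)
  vibrations <- as.numeric(vibrations)
  if (!is.finite(start) || !is.finite(end) || end <= start) {
    stop("exercise_set needs end > start", call. = FALSE)
  }
  if (length(vibrations)) {
    if (any(diff(vibrations) <= 0)) {
      stop("vibration times must be strictly increasing", call. = FALSE)
    }
    if (min(vibrations) < start || max(vibrations) > end) {
      stop(sprintf("vibration time outside set bounds [%g, %g] for %s",
                   start, end, label), call. = FALSE)
    }
  }
  if (!is.na(declared_reps)) {
    declared_reps <- as.integer(declared_reps)
    if (declared_reps < 0L) stop("declared_reps must be nonnegative", call. = FALSE)
    if (length(vibrations) && declared_reps != length(vibrations)) {
      stop("declared_reps must equal the number of vibration times", call. = FALSE)
    }
  } else {
    declared_reps <- NA_integer_
  }
  structure(list(label = label, start = start, end = end,
                 vibrations = vibrations, declared_reps = declared_reps),
            class = "exercise_set")
}

#' Create a workout session
#'
#' @param participant_id Participant identifier (string).
#' @param sets List of [exercise_set()] objects, ordered by start time, with
#'   non-overlapping time ranges.
#' @param streams List of [sensor_stream()] objects covering all sets.
#' @param experience `"beginner"`, `"intermediate"`, `"advanced"` or
#'   `"unknown"`.
#' @return An object of class `wod_session`.
#' @export
wod_session <- function(participant_id, sets, streams,
                        experience = "unknown") {
  experience <- match.arg(experience,
                          c("beginner", "intermediate", "advanced", "unknown"))
  participant_id <- as.character(participant_id)
  stopifnot(is.list(sets), is.list(streams))
  for (s in sets) stopifnot(inherits(s, "exercise_set"))
  for (s in streams) stopifnot(inherits(s, "sensor_stream"))
  if (length(sets) >= 1L) {
    starts <- vapply(sets, `[[`, numeric(1), "start")
    ends <- vapply(sets, `[[`, numeric(1), "end")
    o <- order(starts)
    sets <- sets[o]; starts <- starts[o]; ends <- ends[o]
    if (length(sets) > 1L && any(starts[-1] < ends[-length(ends)])) {
      stop("set time ranges overlap", call. = FALSE)
    }
    if (length(streams)) {
      cov_lo <- max(vapply(streams, function(s) s$time[1], numeric(1)))
      cov_hi <- min(vapply(streams, function(s) s$time[length(s$time)],
                           numeric(1)))
      if (min(starts) < cov_lo - 1e-9 || max(ends) > cov_hi + 1e-9) {
        stop("set time ranges extend beyond stream coverage", call. = FALSE)
      }
    }
  }
  keys <- vapply(streams, stream_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (device, sensor) stream", call. = FALSE)
  }
  names(streams) <- keys
  structure(list(participant_id = participant_id, experience = experience,
                 sets = sets, streams = streams),
            class = "wod_session")
}

#' @export
print.wod_session <- function(x, ...) {
  labs <- vapply(x$sets, `[[`, character(1), "label")
  cat(sprintf("<wod_session> participant %s (%s): %d sets [%s], %d streams\n",
              x$participant_id, x$experience, length(x$sets),
              paste(labs, collapse = " "), length(x$streams)))
  invisible(x)
}

#' Fetch one stream of a session
#'
#' @param session A [wod_session()].
#' @param device,sensor Stream selector.
#' @return The matching [sensor_stream()], or an error naming the pair.
#' @export
get_stream <- function(session, device, sensor) {
  key <- paste(device, sensor, sep = "_")
  s <- session$streams[[key]]
  if (is.null(s)) {
    stop(sprintf("session %s has no (%s, %s) stream",
                 session$participant_id, device, sensor), call. = FALSE)
  }
  s
}
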