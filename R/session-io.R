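## On-disk session format: a JSON manifest (participant, experience, sets)
## plus one CSV per (device, sensor) stream with header t,x,y,z.

#' Write a session to a directory
#'
#' Serializes a session as `manifest.json` plus one `<device>_<sensor>.csv`
#' file per stream (columns `t,x,y,z`, 15 significant digits).
#' `read_session(write_session(s, path))` reproduces `s` up to floating-point
#' text representation.
#'
#' @param session A [wod_session()].
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "wod_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory ", path, call. = FALSE)
  sets <- lapply(session$sets, function(s) {
    list(label = s$label, start = s$start, end = s$end,
         vibrations = as.numeric(s$vibrations),
         declared_reps = if (is.na(s$declared_reps)) NULL else s$declared_reps)
  })
  streams <- lapply(unname(session$streams), function(s) {
    list(device = s$device, sensor = s$sensor,
         file = paste0(stream_key(s), ".csv"))
  })
  manifest <- list(participant_id = session$participant_id,
                   experience = session$experience,
                   sets = sets, streams = streams)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (s in session$streams) {
    df <- data.frame(t = format(s$time, digits = 15, scientific = FALSE,
                                trim = TRUE),
                     x = format(s$values[, 1], digits = 15, trim = TRUE),
                     y = format(s$values[, 2], digits = 15, trim = TRUE),
                     z = format(s$values[, 3], digits = 15, trim = TRUE))
    utils::write.csv(df, file.path(path, paste0(stream_key(s), ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a session from a directory
#'
#' Counterpart of [write_session()]. Stream files with an unknown device or
#' sensor are skipped with a warning; a missing manifest or non-monotone
#' timestamps raise errors.
#'
#' @param path Directory containing `manifest.json` and stream CSVs.
#' @return A [wod_session()].
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    stop("not a session directory (missing manifest.json): ", path,
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  sets <- lapply(manifest$sets, function(s) {
    dr <- unlist(s$declared_reps)
    exercise_set(label = s$label, start = s$start, end = s$end,
                 vibrations = unlist(s$vibrations),
                 declared_reps = if (!length(dr)) NA_integer_ else dr)
  })
  streams <- list()
  for (st in manifest$streams) {
    if (!st$device %in% DEVICES || !st$sensor %in% SENSORS) {
      warning(sprintf("ignoring unknown stream (%s, %s) in %s",
                      st$device, st$sensor, path), call. = FALSE)
      next
    }
    f <- file.path(path, st$file)
    if (!file.exists(f)) {
      stop("stream file missing: ", f, call. = FALSE)
    }
    df <- utils::read.csv(f)
    if (!all(c("t", "x", "y", "z") %in% names(df))) {
      stop("stream file lacks t,x,y,z columns: ", f, call. = FALSE)
    }
    streams[[length(streams) + 1L]] <-
      sensor_stream(st$device, st$sensor, df$t,
                    as.matrix(df[, c("x", "y", "z")]))
  }
  wod_session(participant_id = manifest$participant_id,
              sets = sets, streams = streams,
              experience = manifest$experience %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a list of sessions
#'
#' One subdirectory per session, named by participant id.
#'
#' @param sessions List of [wod_session()] objects.
#' @param path Parent directory.
#' @return `write_sessions()`: `path` invisibly; `read_sessions()`: list of
#'   sessions, ordered by directory name.
#' @export
write_sessions <- function(sessions, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (s in sessions) {
    write_session(s, file.path(path, paste0("session_", s$participant_id)))
  }
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  dirs <- sort(list.dirs(path, recursive = FALSE))
  dirs <- dirs[file.exists(file.path(dirs, "manifest.json"))]
  lapply(dirs, read_session)
}
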