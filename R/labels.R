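## Exercise vocabulary and the canonical channel order shared across the
## package. Ten full-body exercises (push-up ... kettlebell thruster) plus a
## non-exercise ("null") class covering sitting, standing and walking.

#' Exercise codes
#'
#' The ten supported exercise codes, in canonical order. `"null"` denotes the
#' non-exercise class (sitting, standing, walking between sets).
#'
#' @return Character vector `c("E1", ..., "E10")`.
#' @export
exercise_codes <- function() paste0("E", 1:10)

#' @rdname exercise_codes
#' @export
null_label <- function() "null"

#' Human-readable exercise names
#'
#' @return Named character vector mapping codes to exercise names.
#' @export
exercise_names <- function() {
  c(E1 = "push-up", E2 = "pull-up", E3 = "burpee",
    E4 = "kettlebell deadlift", E5 = "box jump", E6 = "air squat",
    E7 = "sit-up", E8 = "wall ball", E9 = "kettlebell press",
    E10 = "kettlebell thruster")
}

DEVICES <- c("wrist", "ankle")
SENSORS <- c("accelerometer", "gyroscope", "orientation")
AXES <- c("x", "y", "z")

#' Canonical channel order
#'
#' Channels are always ordered wrist before ankle, then accelerometer,
#' gyroscope, orientation, then axes x, y, z, so that the three axes of one
#' sensor are contiguous (the first convolution layer strides over axis
#' triplets and must never straddle two sensors).
#'
#' @param selection Optional data.frame with columns `device` and `sensor`
#'   restricting the order to a subset of (device, sensor) pairs.
#' @return data.frame with columns `device`, `sensor`, `axis`, one row per
#'   channel.
#' @export
canonical_channel_order <- function(selection = NULL) {
  full <- expand.grid(axis = AXES, sensor = SENSORS, device = DEVICES,
                      stringsAsFactors = FALSE)[, c("device", "sensor", "axis")]
  ## expand.grid varies the first factor fastest, hence axis innermost
  if (is.null(selection)) return(full)
  stopifnot(all(c("device", "sensor") %in% names(selection)))
  keep <- paste(full$device, full$sensor) %in%
    paste(selection$device, selection$sensor)
  out <- full[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' All six (device, sensor) pairs
#'
#' @return data.frame with columns `device` and `sensor` in canonical order.
#' @export
all_sensor_pairs <- function() {
  unique(canonical_channel_order()[, c("device", "sensor")])
}

match_label <- function(label, allow_null = TRUE) {
  ok <- c(exercise_codes(), if (allow_null) null_label())
  if (!is.character(label) || length(label) != 1L || !label %in% ok) {
    stop("invalid exercise label: ", deparse(label), call. = FALSE)
  }
  label
}
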