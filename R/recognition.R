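## Fusing per-window predictions into a per-time-step label sequence:
## majority voting over all windows covering a time step, then smoothing of
## implausibly short runs against per-exercise minimum repetition durations.

#' Majority vote over overlapping window predictions
#'
#' Every time step takes the most frequent label among all windows covering
#' it (hard votes over argmax labels). Vote ties go to the class that comes
#' first in `classes`. Steps covered by no window inherit the label of the
#' nearest covered step (ties to the earlier side).
#'
#' @param starts Integer vector of 0-based window start offsets (samples).
#' @param labels Character vector of per-window predicted labels.
#' @param W Window length in samples.
#' @param seq_len Length of the output sequence in samples.
#' @param classes Class order used for tie-breaking (default: E1..E10, null).
#' @return Character vector of length `seq_len`.
#' @export
majority_vote <- function(starts, labels, W, seq_len,
                          classes = c(exercise_codes(), null_label())) {
  if (length(starts) == 0L) stop("empty window list", call. = FALSE)
  if (length(starts) != length(labels)) {
    stop("starts and labels lengths differ", call. = FALSE)
  }
  if (any(starts < 0L) || any(starts + W > seq_len)) {
    stop("window outside [0, seq_len)", call. = FALSE)
  }
  if (!all(labels %in% classes)) stop("labels outside the class set", call. = FALSE)
  K <- length(classes)
  votes <- matrix(0L, seq_len, K)
  li <- match(labels, classes)
  for (i in seq_along(starts)) {       # difference trick: O(windows + steps)
    votes[starts[i] + 1L, li[i]] <- votes[starts[i] + 1L, li[i]] + 1L
    if (starts[i] + W < seq_len) {
      votes[starts[i] + W + 1L, li[i]] <- votes[starts[i] + W + 1L, li[i]] - 1L
    }
  }
  votes <- apply(votes, 2, cumsum)
  votes <- matrix(votes, seq_len, K)
  covered <- rowSums(votes) > 0L
  lab_idx <- max.col(votes, ties.method = "first")
  if (!all(covered)) {                 # inherit the nearest covered label
    cov_pos <- which(covered)
    gap <- which(!covered)
    fi <- findInterval(gap, cov_pos)
    left <- ifelse(fi == 0L, NA_integer_, cov_pos[pmax(fi, 1L)])
    right <- ifelse(fi >= length(cov_pos), NA_integer_,
                    cov_pos[pmin(fi + 1L, length(cov_pos))])
    d_left <- gap - left
    d_right <- right - gap
    nearest <- ifelse(!is.na(d_right) & (is.na(d_left) | d_right < d_left),
                      right, left)                    # ties -> earlier side
    lab_idx[gap] <- lab_idx[nearest]
  }
  classes[lab_idx]
}

#' Smooth a label sequence with minimum repetition durations
#'
#' Finds every maximal run of a non-null label `Ek` flanked on both sides by
#' one identical label `Ej` (which may be null) and replaces it with `Ej`
#' when its duration falls below the minimum repetition duration
#' `t_min[Ek]`. Runs at the sequence boundaries (only one flank) are left
#' unchanged, and null runs are never replaced. The rule is applied to a
#' fixpoint, shortest run first, which makes the result unique; the
#' operation is idempotent.
#'
#' @param labels Character vector of per-step labels.
#' @param cfg An [exercise_config()] supplying `t_min` for every non-null
#'   label present.
#' @param resolution Seconds per step of `labels`.
#' @return Smoothed character vector, same length.
#' @export
smooth_labels <- function(labels, cfg, resolution) {
  stopifnot(inherits(cfg, "exercise_config"), resolution > 0)
  seen <- setdiff(unique(labels), null_label())
  missing <- setdiff(seen, names(cfg$t_min))
  if (length(missing)) {
    stop("no t_min configured for label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  repeat {
    r <- rle(labels)
    nr <- length(r$lengths)
    if (nr < 3L) return(labels)
    i <- 2:(nr - 1L)
    cand <- i[r$values[i] != null_label() &
              r$values[i - 1L] == r$values[i + 1L] &
              r$values[i - 1L] != r$values[i] &
              r$lengths[i] * resolution < cfg$t_min[r$values[i]] - 1e-12]
    if (!length(cand)) return(labels)
    pick <- cand[which.min(r$lengths[cand])]
    r$values[pick] <- r$values[pick - 1L]
    labels <- inverse.rle(r)
  }
}

#' Segment a smoothed label sequence into exercise sets
#'
#' Maximal constant-label runs, null runs excluded, ordered by start. Each
#' segment is then routed to the repetition-counting model of its exercise.
#'
#' @param labels Character vector of per-step labels.
#' @param resolution Seconds per step.
#' @param t0 Time of the first step in seconds (default 0).
#' @return data.frame with columns `label`, `start`, `end` (seconds,
#'   half-open) and `start_step`, `end_step` (1-based step indices,
#'   inclusive).
#' @export
segment_sets <- function(labels, resolution = 1, t0 = 0) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != null_label()
  data.frame(label = r$values[keep],
             start = t0 + (starts[keep] - 1L) * resolution,
             end = t0 + ends[keep] * resolution,
             start_step = starts[keep], end_step = ends[keep],
             stringsAsFactors = FALSE)
}

#' Export segments as a tab-separated file
#'
#' @param segments data.frame from [segment_sets()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments[, c("label", "start", "end")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
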