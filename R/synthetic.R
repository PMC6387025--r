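## Seeded synthetic workout generator. Emulates the statistical structure the
## pipeline assumes: ~100 Hz jittered sampling on two watches x three sensors,
## per-exercise quasi-periodic 18-channel signatures (sums of harmonics of the
## repetition frequency with class-specific channel loadings, an onset burst
## at each repetition start, and a within-repetition activity envelope),
## per-subject amplitude/phase/period variation, vibration-annotated
## repetition starts, and an aperiodic null class (slow wander + noise).

#' Synthetic workout configuration
#'
#' Defaults emulate the constrained data-collection protocol: one set of 15
#' repetitions per exercise per subject, repetition intervals between 1.5 and
#' 4 s, 90-120 s of null (sit/stand/walk) activity, sampling at a nominal
#' 100 Hz with timestamp jitter.
#'
#' @param n_subjects Number of subjects (default 12).
#' @param exercises Exercise codes to simulate (default all ten).
#' @param reps_per_set Repetitions per constrained set (default 15).
#' @param rep_interval Range (seconds) from which each exercise's fundamental
#'   repetition interval is drawn (default `c(1.5, 4)`).
#' @param n_harmonics Harmonics per class signature (default 3).
#' @param amp Oscillation amplitude scale in signal units (default 2).
#' @param subject_amp_sd,subject_phase_sd,subject_period_sd Log-amplitude,
#'   phase (radians) and log-period scales of per-subject variation.
#' @param noise_sd White measurement noise s.d. (signal units).
#' @param wander_sd,wander_theta Marginal s.d. and mean-reversion rate (1/s)
#'   of the slow baseline wander present in all signals (the only structure
#'   of the null class). The defaults keep the wander well below the
#'   exercise frequency band (0.25-0.67 Hz fundamentals) so null segments
#'   show no periodic structure above the noise floor.
#' @param jitter_sd Timestamp jitter s.d. (seconds) around the 10 ms step.
#' @param rate Nominal sampling rate in Hz (default 100).
#' @param null_duration Range (seconds) of the explicit null set.
#' @param gap_duration Range (seconds) of inter-set transition gaps.
#' @param burst,burst_width Onset-burst gain and width (fraction of the
#'   repetition) marking each repetition start.
#' @param active_fraction Fraction of each constrained repetition interval
#'   spent moving before the wait for the next vibration.
#' @param seed Master seed; a fixed seed makes generation byte-identical.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 12, exercises = exercise_codes(),
                             reps_per_set = 15, rep_interval = c(1.5, 4),
                             n_harmonics = 3, amp = 2,
                             subject_amp_sd = 0.15, subject_phase_sd = 0.25,
                             subject_period_sd = 0.05, noise_sd = 0.3,
                             wander_sd = 0.08, wander_theta = 0.05,
                             jitter_sd = 0.0015, rate = 100,
                             null_duration = c(90, 120),
                             gap_duration = c(4, 8),
                             burst = 1.25, burst_width = 0.12,
                             active_fraction = 0.75, seed = 42) {
  stopifnot(n_subjects >= 1, reps_per_set >= 1,
            length(rep_interval) == 2L, all(rep_interval > 0),
            rep_interval[1] <= rep_interval[2],
            n_harmonics >= 1, amp >= 0, subject_amp_sd >= 0,
            subject_phase_sd >= 0, subject_period_sd >= 0, noise_sd >= 0,
            wander_sd >= 0, wander_theta > 0, jitter_sd >= 0, rate > 0,
            all(exercises %in% exercise_codes()))
  structure(as.list(environment()), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config> %d subjects, %d exercises + null, ",
                     "%d reps/set, intervals %.1f-%.1f s, seed %d\n"),
              x$n_subjects, length(x$exercises), x$reps_per_set,
              x$rep_interval[1], x$rep_interval[2], x$seed))
  invisible(x)
}

## Class signatures: fixed pseudo-random loadings drawn once from the master
## seed; distinct periods and channel loadings guarantee class separability
## without hand-designed biomechanical waveforms.
draw_signatures <- function(cfg) {
  n_ch <- 18L
  sig <- list()
  for (ex in cfg$exercises) {
    sig[[ex]] <- list(
      period = stats::runif(1, cfg$rep_interval[1], cfg$rep_interval[2]),
      loadings = matrix(stats::rnorm(cfg$n_harmonics * n_ch, sd = cfg$amp),
                        cfg$n_harmonics, n_ch) /
                 matrix(seq_len(cfg$n_harmonics), cfg$n_harmonics, n_ch),
      phases = matrix(stats::runif(cfg$n_harmonics * n_ch, 0, 2 * pi),
                      cfg$n_harmonics, n_ch),
      baseline = stats::rnorm(n_ch, sd = 1.5))
  }
  sig
}

draw_subject <- function(cfg, i) {
  list(id = sprintf("S%02d", i),
       experience = sample(c("beginner", "intermediate", "advanced"), 1),
       amp = exp(stats::rnorm(1, 0, cfg$subject_amp_sd)),
       phase = stats::rnorm(1, 0, cfg$subject_phase_sd),
       period_factor = exp(stats::rnorm(1, 0, cfg$subject_period_sd)))
}

## One subject's workout schedule for a scheme. Returns set descriptors with
## true repetition starts and per-repetition durations.
draw_schedule <- function(cfg, subject, scheme) {
  reps_rounds <- switch(scheme,
    constrained = list(cfg$reps_per_set),
    free10 = list(10L),
    one_two_three = list(1L, 2L, 3L))
  constrained <- scheme == "constrained"
  sets <- list()
  t <- stats::runif(1, cfg$gap_duration[1], cfg$gap_duration[2])
  order_classes <- sample(cfg$exercises)
  null_slot <- sample(length(order_classes) * length(reps_rounds), 1)
  k <- 0L
  for (round_reps in reps_rounds) {
    for (ex in order_classes) {
      k <- k + 1L
      p <- subject$period_factor *
        if (constrained) subject$period_ex[[ex]] else 0.8 * subject$period_ex[[ex]]
      n <- round_reps
      durations <- if (constrained) rep(p, n) else p * exp(stats::rnorm(n, 0, 0.05))
      starts <- t + c(0, cumsum(durations[-n]))
      end <- t + sum(durations)
      sets[[length(sets) + 1L]] <- list(
        label = ex, start = t, end = end, rep_starts = starts,
        durations = durations, n_reps = n, constrained = constrained)
      t <- end + stats::runif(1, cfg$gap_duration[1], cfg$gap_duration[2])
      if (k == null_slot) {
        dur <- stats::runif(1, cfg$null_duration[1], cfg$null_duration[2])
        sets[[length(sets) + 1L]] <- list(
          label = null_label(), start = t, end = t + dur,
          rep_starts = numeric(), durations = numeric(), n_reps = 0L,
          constrained = constrained)
        t <- t + dur + stats::runif(1, cfg$gap_duration[1], cfg$gap_duration[2])
      }
    }
  }
  list(sets = sets, t_end = t)
}

#' Simulate workout schedules without synthesizing signals
#'
#' Draws the per-subject set schedules (labels, boundaries, true repetition
#' start times and per-repetition durations) that [generate_dataset()] turns
#' into sensor signals. Useful when only the annotation geometry is needed,
#' e.g. for large-scale checks of the window-labeling and counting logic.
#'
#' @param cfg A [synthetic_config()].
#' @param scheme `"constrained"`, `"free10"` or `"one_two_three"`.
#' @return List of per-subject plans: `list(subject, sets, t_end)`.
#' @export
simulate_workout_plan <- function(cfg, scheme = c("constrained", "free10",
                                                  "one_two_three")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(cfg, "synthetic_config"))
  withr_seed(cfg$seed, {
    sig <- draw_signatures(cfg)
    lapply(seq_len(cfg$n_subjects), function(i) {
      subject <- draw_subject(cfg, i)
      subject$period_ex <- lapply(sig, `[[`, "period")
      sched <- draw_schedule(cfg, subject, scheme)
      list(subject = subject, sets = sched$sets, t_end = sched$t_end)
    })
  })
}

## slow mean-reverting wander evaluated at (approximately uniform) times
wander_path <- function(n, dt, cfg) {
  a <- exp(-cfg$wander_theta * dt)
  innov <- stats::rnorm(n, 0, cfg$wander_sd * sqrt(1 - a^2))
  innov[1] <- stats::rnorm(1, 0, cfg$wander_sd)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

## oscillatory exercise component for channels chs at times tt inside one set
set_oscillation <- function(tt, set, sig, subject, cfg, chs) {
  vs <- set$rep_starts
  d <- set$durations
  j <- pmin(pmax(findInterval(tt, vs), 1L), length(vs))
  u <- (tt - vs[j]) / d[j]
  u <- pmin(pmax(u, 0), 1)
  phase <- (j - 1L) + u                       # cumulative repetition phase
  rho <- if (set$constrained) cfg$active_fraction else 1
  act <- ifelse(u <= rho, 1,
                0.15 + 0.85 * (1 + cos(pi * (u - rho) / max(1 - rho, 1e-9))) / 2)
  env <- act * (1 + cfg$burst * exp(-(u / cfg$burst_width)^2))
  out <- matrix(0, length(tt), length(chs))
  L <- sig$loadings; P <- sig$phases
  for (ci in seq_along(chs)) {
    ch <- chs[ci]
    osc <- 0
    for (h in seq_len(cfg$n_harmonics)) {
      osc <- osc + L[h, ch] * sin(2 * pi * h * phase + P[h, ch] + subject$phase)
    }
    out[, ci] <- sig$baseline[ch] + subject$amp * env * osc
  }
  out
}

#' Generate a synthetic workout dataset
#'
#' Produces one annotated session per subject. Constrained sessions carry
#' vibration annotations at every repetition start; unconstrained schemes
#' (`"free10"`, `"one_two_three"`) carry declared repetition counts only,
#' with the hidden true starts retained for evaluation (see
#' [ground_truth_table()]). Generation is fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param scheme `"constrained"` (default), `"free10"` or `"one_two_three"`.
#' @return List of [wod_session()] objects.
#' @export
generate_dataset <- function(cfg, scheme = c("constrained", "free10",
                                             "one_two_three")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(cfg, "synthetic_config"))
  withr_seed(cfg$seed, {
    sig <- draw_signatures(cfg)
    sessions <- vector("list", cfg$n_subjects)
    pairs <- all_sensor_pairs()
    order_df <- canonical_channel_order()
    for (i in seq_len(cfg$n_subjects)) {
      subject <- draw_subject(cfg, i)
      subject$period_ex <- lapply(sig, `[[`, "period")
      sched <- draw_schedule(cfg, subject, scheme)
      streams <- list()
      for (pi in seq_len(nrow(pairs))) {
        dev <- pairs$device[pi]; sen <- pairs$sensor[pi]
        chs <- which(order_df$device == dev & order_df$sensor == sen)
        ## jittered ~100 Hz timestamps covering the whole session
        lead <- 0.5
        n_t <- as.integer(ceiling((sched$t_end + 2 * lead) * cfg$rate)) + 2L
        dt <- pmax(0.2 / cfg$rate,
                   stats::rnorm(n_t, 1 / cfg$rate, cfg$jitter_sd))
        tt <- -lead + cumsum(dt)
        tt <- tt[tt <= sched$t_end + lead]
        vals <- vapply(seq_along(chs), function(ci) {
          wander_path(length(tt), 1 / cfg$rate, cfg) +
            stats::rnorm(length(tt), 0, cfg$noise_sd)
        }, numeric(length(tt)))
        vals <- matrix(vals, ncol = length(chs))
        for (set in sched$sets) {
          if (set$label == null_label()) next
          inside <- tt >= set$start & tt <= set$end
          if (!any(inside)) next
          vals[inside, ] <- vals[inside, ] +
            set_oscillation(tt[inside], set, sig[[set$label]], subject, cfg, chs)
        }
        streams[[length(streams) + 1L]] <- sensor_stream(dev, sen, tt, vals)
      }
      sets <- lapply(sched$sets, function(s) {
        es <- exercise_set(
          label = s$label, start = s$start, end = s$end,
          vibrations = if (s$constrained && s$label != null_label())
            s$rep_starts else numeric(),
          declared_reps = if (s$label == null_label()) NA_integer_ else s$n_reps)
        attr(es, "true_starts") <- s$rep_starts
        es
      })
      sessions[[i]] <- wod_session(subject$id, sets, streams,
                                   experience = subject$experience)
    }
    sessions
  })
}

#' Generate a standalone null-activity segment
#'
#' Sit/stand/walk filler: a slow mean-reverting wander plus white noise, with
#' no periodic structure in the exercise frequency band.
#'
#' @param duration_s Duration in seconds.
#' @param cfg A [synthetic_config()].
#' @param n_channels Number of channels (default 18).
#' @return List with `time` (jittered ~100 Hz timestamps) and `values`
#'   (matrix, `n_channels` columns).
#' @export
generate_null_segment <- function(duration_s, cfg = synthetic_config(),
                                  n_channels = 18) {
  stopifnot(duration_s > 0)
  n_t <- as.integer(ceiling(duration_s * cfg$rate)) + 1L
  dt <- pmax(0.2 / cfg$rate, stats::rnorm(n_t, 1 / cfg$rate, cfg$jitter_sd))
  tt <- cumsum(dt) - dt[1]
  tt <- tt[tt <= duration_s]
  vals <- vapply(seq_len(n_channels), function(ci) {
    wander_path(length(tt), 1 / cfg$rate, cfg) +
      stats::rnorm(length(tt), 0, cfg$noise_sd)
  }, numeric(length(tt)))
  list(time = tt, values = matrix(vals, ncol = n_channels))
}

#' Ground-truth table of generated sessions
#'
#' One row per non-null set with the true label, boundaries, repetition
#' starts (hidden starts for unconstrained schemes) and true count.
#'
#' @param sessions Sessions from [generate_dataset()].
#' @return data.frame with columns `participant`, `set`, `label`, `start`,
#'   `end`, `n_reps`, and a list-column `rep_starts`.
#' @export
ground_truth_table <- function(sessions) {
  rows <- list()
  for (sess in sessions) {
    for (si in seq_along(sess$sets)) {
      set <- sess$sets[[si]]
      if (set$label == null_label()) next
      starts <- attr(set, "true_starts")
      if (is.null(starts)) starts <- set$vibrations
      rows[[length(rows) + 1L]] <- data.frame(
        participant = sess$participant_id, set = si, label = set$label,
        start = set$start, end = set$end,
        n_reps = if (!is.na(set$declared_reps)) set$declared_reps
                 else length(starts))
      rows[[length(rows)]]$rep_starts <- I(list(starts))
    }
  }
  do.call(rbind, rows)
}
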