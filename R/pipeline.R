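## High-level pipeline: window pools, recognizer / counter training,
## subject-grouped evaluation, and full workout tracking
## (recognize -> segment -> count).

#' Build a labeled recognition window pool from sessions
#'
#' Resamples each session onto the 100 Hz grid, stacks the selected sensors,
#' extracts windows of `T_s` seconds at overlap `gamma`, and labels each
#' window by majority set coverage (null when no set covers a majority).
#'
#' @param sessions List of [wod_session()] objects.
#' @param selection Sensor selection (default: all six (device, sensor) pairs).
#' @param T_s Window length in seconds (default 4).
#' @param gamma Overlap factor between consecutive pool windows (default 0).
#' @param rate Sampling rate in Hz.
#' @return List with `x` (array `W x C x n`), `y` (labels), `participant`.
#' @export
recognition_pool <- function(sessions, selection = all_sensor_pairs(),
                             T_s = 4, gamma = 0, rate = 100) {
  W <- as.integer(round(T_s * rate))
  stride <- compute_stride(W, gamma)
  xs <- list(); ys <- list(); ps <- list()
  for (sess in sessions) {
    cm <- assemble_channels(sess, selection, rate = rate)
    ws <- extract_windows(cm, W, stride)
    if (!n_windows(ws)) next
    xs[[length(xs) + 1L]] <- ws$data
    ys[[length(ys) + 1L]] <- label_recognition_windows(ws, sess)
    ps[[length(ps) + 1L]] <- rep(sess$participant_id, n_windows(ws))
  }
  if (!length(xs)) stop("no windows could be extracted", call. = FALSE)
  ns <- vapply(xs, function(a) dim(a)[3], integer(1))
  x <- array(0, c(dim(xs[[1]])[1:2], sum(ns)))
  at <- 0L
  for (i in seq_along(xs)) {
    x[, , at + seq_len(ns[i])] <- xs[[i]]
    at <- at + ns[i]
  }
  list(x = x, y = unlist(ys), participant = unlist(ps))
}

#' Train the exercise recognition network
#'
#' @param sessions Training sessions.
#' @param spec,control Model and training configuration.
#' @param classes Class set (default: exercises present plus null).
#' @inheritParams recognition_pool
#' @param validation Optional validation pool passed to [har_cnn()].
#' @return A fitted [har_cnn()].
#' @export
train_recognizer <- function(sessions, spec = model_spec(),
                             control = train_control(),
                             selection = all_sensor_pairs(), T_s = 4,
                             gamma = 0, rate = 100, classes = NULL,
                             validation = NULL) {
  pool <- recognition_pool(sessions, selection, T_s, gamma, rate)
  if (is.null(classes)) {
    classes <- c(intersect(exercise_codes(), unique(pool$y)),
                 if (null_label() %in% pool$y) null_label())
  }
  har_cnn(pool$x, pool$y, spec = spec, control = control,
          validation = validation, classes = classes)
}

#' Build a counting window pool for one exercise
#'
#' Extracts windows of the exercise-specific length `w` from every
#' vibration-annotated set of the exercise, at stride
#' `max(1, round(w / stride_divisor))`, labeled 1 iff the window fully
#' contains a repetition-start segment.
#'
#' @param sessions Annotated sessions.
#' @param exercise Exercise code.
#' @param cfg An [exercise_config()].
#' @param selection Sensor selection.
#' @param stride_divisor Pool stride divisor (default 10).
#' @param rate Sampling rate in Hz.
#' @param margin Lead-in/out around each set as a fraction of the counting
#'   window (default 0.5), so start segments at the set boundary are fully
#'   containable.
#' @return List with `x`, `y` (characters `"0"`/`"1"`), `participant`.
#' @export
counting_pool <- function(sessions, exercise, cfg,
                          selection = all_sensor_pairs(),
                          stride_divisor = 10, rate = 100, margin = 0.5) {
  w <- cfg$w[exercise]
  if (is.na(w)) stop("no counting window for ", exercise, call. = FALSE)
  stride <- max(1L, as.integer(round(w / stride_divisor)))
  pad <- margin * w / rate
  xs <- list(); ys <- list(); ps <- list()
  for (sess in sessions) {
    for (set in sess$sets) {
      if (set$label != exercise || !length(set$vibrations)) next
      cov <- common_grid(sess, selection)
      cm <- assemble_channels(sess, selection, rate = rate,
                              grid = c(max(cov[1], set$start - pad),
                                       min(cov[2], set$end + pad)))
      ws <- extract_windows(cm, w, stride)
      if (!n_windows(ws)) next
      xs[[length(xs) + 1L]] <- ws$data
      ys[[length(ys) + 1L]] <- as.character(label_counting_windows(ws, set, cfg))
      ps[[length(ps) + 1L]] <- rep(sess$participant_id, n_windows(ws))
    }
  }
  if (!length(xs)) stop("no counting windows for ", exercise, call. = FALSE)
  ns <- vapply(xs, function(a) dim(a)[3], integer(1))
  x <- array(0, c(dim(xs[[1]])[1:2], sum(ns)))
  at <- 0L
  for (i in seq_along(xs)) {
    x[, , at + seq_len(ns[i])] <- xs[[i]]
    at <- at + ns[i]
  }
  list(x = x, y = unlist(ys), participant = unlist(ps))
}

#' Train per-exercise repetition counting networks
#'
#' One binary start-detection network per exercise, trained on
#' vibration-annotated sets.
#'
#' @param sessions Training sessions.
#' @param cfg An [exercise_config()].
#' @param exercises Exercises to train (default: all with a configured
#'   `t_min`).
#' @param spec,control Model and training configuration.
#' @param selection Sensor selection.
#' @param stride_divisor Pool stride divisor (default 10).
#' @param rate Sampling rate in Hz.
#' @param verbose Print progress.
#' @return Named list of fitted [har_cnn()] models.
#' @export
train_counters <- function(sessions, cfg, exercises = names(cfg$t_min),
                           spec = model_spec(), control = train_control(),
                           selection = all_sensor_pairs(), stride_divisor = 10,
                           rate = 100, verbose = FALSE) {
  models <- list()
  for (ex in exercises) {
    if (verbose) cat("training counter for", ex, "\n")
    pool <- counting_pool(sessions, ex, cfg, selection, stride_divisor, rate)
    models[[ex]] <- har_cnn(pool$x, pool$y, spec = spec, control = control,
                            classes = c("0", "1"))
  }
  models
}

#' Recognize exercises over a whole session
#'
#' Classifies overlapping windows, fuses them by per-sample majority voting,
#' smooths implausibly short runs with the per-exercise minimum durations and
#' segments the result into exercise sets.
#'
#' @param session A [wod_session()].
#' @param model Fitted recognition [har_cnn()].
#' @param cfg An [exercise_config()] (for smoothing).
#' @param selection Sensor selection.
#' @param T_s Window length in seconds (default 4).
#' @param gamma Test-time window overlap (default 0.95).
#' @param rate Sampling rate in Hz.
#' @return List with `labels` (per-sample smoothed sequence), `voted`
#'   (before smoothing), `segments` (data.frame), `t0`, `resolution`.
#' @export
recognize_session <- function(session, model, cfg,
                              selection = all_sensor_pairs(), T_s = 4,
                              gamma = 0.95, rate = 100) {
  W <- as.integer(round(T_s * rate))
  stride <- compute_stride(W, gamma)
  cm <- assemble_channels(session, selection, rate = rate)
  ws <- extract_windows(cm, W, stride)
  pred <- predict(model, ws, type = "class")
  voted <- majority_vote(ws$starts, pred, W, nrow(cm$data),
                         classes = model$classes)
  smoothed <- smooth_labels(voted, cfg, resolution = 1 / rate)
  segs <- segment_sets(smoothed, resolution = 1 / rate, t0 = cm$t0)
  list(labels = smoothed, voted = voted, segments = segs, t0 = cm$t0,
       resolution = 1 / rate)
}

#' Track a full workout: recognize, segment and count
#'
#' The end-to-end pipeline: the recognition network proposes a smoothed label
#' sequence, each resulting segment is routed to the counting network of the
#' recognized exercise, and repetitions are counted from the smoothed binary
#' start sequence.
#'
#' @inheritParams recognize_session
#' @param counters Named list of per-exercise counting [har_cnn()] models.
#' @param threshold Start-probability threshold (default 0.5).
#' @param stride_divisor Counting stride divisor (default 20).
#' @param margin Lead-in/out around each recognized segment as a fraction of
#'   the counting window (default 0.25). Recognized boundaries already bleed
#'   outward by up to half a recognition window through voting, so less
#'   lead-in is needed than for tightly annotated sets (see
#'   [count_annotated_sets()]).
#' @return List with `segments` (data.frame incl. `count`) and `recognition`
#'   (output of [recognize_session()]).
#' @export
track_workout <- function(session, model, counters, cfg,
                          selection = all_sensor_pairs(), T_s = 4,
                          gamma = 0.95, rate = 100, threshold = 0.5,
                          stride_divisor = 20, margin = 0.25) {
  rec <- recognize_session(session, model, cfg, selection, T_s, gamma, rate)
  cm <- assemble_channels(session, selection, rate = rate)
  segs <- rec$segments
  segs$count <- NA_integer_
  for (i in seq_len(nrow(segs))) {
    if (is.null(counters[[segs$label[i]]])) next
    pad <- margin * cfg$w[segs$label[i]] / rate
    sub <- slice_channels(cm, segs$start[i] - pad, segs$end[i] + pad)
    segs$count[i] <- count_segment(sub, segs$label[i], counters, cfg,
                                   threshold = threshold,
                                   stride_divisor = stride_divisor)$count
  }
  list(segments = segs, recognition = rec)
}

#' Subject-grouped cross-validated recognition accuracy
#'
#' Trains one recognizer per fold on the training subjects' windows and
#' scores window-level accuracy on the held-out subjects.
#'
#' @param pool Window pool from [recognition_pool()].
#' @param folds A `fold_plan` over the pool's participants.
#' @param spec,control Model and training configuration.
#' @param classes Class set (default from the pool).
#' @param verbose Print per-fold progress.
#' @return List with `accuracy` (pooled over folds), `per_fold`, `confusion`,
#'   `truth`, `pred`.
#' @export
evaluate_recognition <- function(pool, folds, spec = model_spec(),
                                 control = train_control(), classes = NULL,
                                 verbose = FALSE) {
  stopifnot(inherits(folds, "fold_plan"))
  if (is.null(classes)) {
    classes <- c(intersect(exercise_codes(), unique(pool$y)),
                 if (null_label() %in% pool$y) null_label())
  }
  truth <- character(); pred <- character(); per_fold <- numeric(length(folds))
  for (fi in seq_along(folds)) {
    tr <- pool$participant %in% folds[[fi]]$train
    te <- pool$participant %in% folds[[fi]]$test
    fit <- har_cnn(pool$x[, , tr, drop = FALSE], pool$y[tr], spec = spec,
                   control = control, classes = classes)
    p <- predict(fit, pool$x[, , te, drop = FALSE], type = "class")
    per_fold[fi] <- mean(p == pool$y[te])
    truth <- c(truth, pool$y[te]); pred <- c(pred, p)
    if (verbose) cat(sprintf("fold %d: window accuracy %.4f\n",
                             fi, per_fold[fi]))
  }
  acc <- accuracy_and_confusion(truth, pred, classes)
  list(accuracy = acc$accuracy, per_fold = per_fold,
       confusion = acc$confusion, truth = truth, pred = pred)
}

#' Count repetitions of annotated sets with trained counters
#'
#' Evaluates counting on sets whose true label is known (counting given
#' correct recognition): each set's channel slice is counted by its
#' exercise's network and compared with the declared repetition count.
#'
#' @param sessions Sessions to evaluate.
#' @param models Named list of counting models.
#' @param cfg An [exercise_config()].
#' @param selection Sensor selection.
#' @param rate Sampling rate in Hz.
#' @param threshold,stride_divisor Passed to [count_segment()].
#' @param margin Lead-in/out around each segment, as a fraction of the
#'   counting window (default 0.5): a repetition starting exactly at the
#'   segment boundary is only containable by windows that begin half a
#'   window earlier.
#' @return data.frame with `participant`, `label`, `pred`, `truth`.
#' @export
count_annotated_sets <- function(sessions, models, cfg,
                                 selection = all_sensor_pairs(), rate = 100,
                                 threshold = 0.5, stride_divisor = 20,
                                 margin = 0.5) {
  rows <- list()
  for (sess in sessions) {
    cm <- assemble_channels(sess, selection, rate = rate)
    for (set in sess$sets) {
      if (set$label == null_label() || is.null(models[[set$label]])) next
      truth <- if (!is.na(set$declared_reps)) set$declared_reps
               else length(attr(set, "true_starts"))
      pad <- margin * cfg$w[set$label] / rate
      sub <- slice_channels(cm, set$start - pad, set$end + pad)
      res <- count_segment(sub, set$label, models, cfg,
                           threshold = threshold,
                           stride_divisor = stride_divisor)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = sess$participant_id, label = set$label,
        pred = res$count, truth = truth)
    }
  }
  do.call(rbind, rows)
}

#' Synthetic end-to-end benchmark
#'
#' The package's standing study on synthetic data: subject-grouped 5-fold
#' cross-validated window recognition accuracy, and repetition counting on a
#' grouped holdout (the last two subjects held out, per-exercise counters
#' trained on the rest), with the counting error metrics. Problem sizes are
#' kept at desk scale: a reduced filter configuration and short SGD budgets
#' (see the methods vignette).
#'
#' @param cfg A [synthetic_config()] (default: 12 subjects, seed 42).
#' @param train_seed Seed for fold assignment and network training.
#' @param recognition_epochs,counting_epochs SGD epochs (defaults 15 and 8,
#'   at 25 batches per epoch).
#' @param verbose Print progress.
#' @return List with `recognition` (from [evaluate_recognition()]),
#'   `counting` (per-set table + [counting_metrics()]), `config` and
#'   `exercise_config`.
#' @export
synthetic_benchmark <- function(cfg = synthetic_config(), train_seed = 1,
                                recognition_epochs = 15, counting_epochs = 8,
                                verbose = FALSE) {
  sessions <- generate_dataset(cfg, scheme = "constrained")
  excfg <- estimate_exercise_config(sessions, rate = cfg$rate)
  spec_rec <- model_spec(filters = c(16, 8), dense = 32, dropout = 0.2)
  ctrl_rec <- train_control(batch_size = 30, learning_rate = 0.02,
                            max_epochs = recognition_epochs,
                            batches_per_epoch = 25, seed = train_seed)
  pool <- recognition_pool(sessions, T_s = 4, gamma = 0, rate = cfg$rate)
  folds <- grouped_kfold(unique(pool$participant), k = 5, seed = train_seed)
  rec <- evaluate_recognition(pool, folds, spec = spec_rec, control = ctrl_rec,
                              verbose = verbose)
  ids <- vapply(sessions, `[[`, character(1), "participant_id")
  test_ids <- utils::tail(sort(ids), 2)
  train_sessions <- sessions[!ids %in% test_ids]
  test_sessions <- sessions[ids %in% test_ids]
  spec_cnt <- model_spec(filters = c(12, 8), dense = 24, dropout = 0.2)
  ctrl_cnt <- train_control(batch_size = 30, learning_rate = 0.02,
                            max_epochs = counting_epochs,
                            batches_per_epoch = 25, seed = train_seed + 1)
  counters <- train_counters(train_sessions, excfg, spec = spec_cnt,
                             control = ctrl_cnt, stride_divisor = 10,
                             rate = cfg$rate, verbose = verbose)
  counts <- count_annotated_sets(test_sessions, counters, excfg,
                                 rate = cfg$rate)
  metrics <- counting_metrics(counts$pred, counts$truth)
  list(recognition = rec,
       counting = list(per_set = counts, metrics = metrics,
                       within_1 = mean(abs(counts$pred - counts$truth) <= 1)),
       config = cfg, exercise_config = excfg)
}
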