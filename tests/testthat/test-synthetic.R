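test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_subjects = 2, reps_per_set = 4,
                          exercises = c("E1", "E5"),
                          null_duration = c(10, 15), gap_duration = c(2, 3),
                          seed = 7)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_equal(length(a), 2L)
  for (i in 1:2) expect_sessions_equal(a[[i]], b[[i]], tol = 0)
  ## serialized output is byte-identical
  da <- withr::local_tempdir(); db <- withr::local_tempdir()
  write_sessions(a, da); write_sessions(b, db)
  fa <- list.files(da, recursive = TRUE)
  expect_true(all(mapply(function(f) {
    identical(readLines(file.path(da, f)), readLines(file.path(db, f)))
  }, fa)))
})

test_that("constrained sets carry one vibration per repetition", {
  sm <- small_dataset()
  for (sess in sm$sessions) {
    ex_sets <- Filter(function(s) s$label != null_label(), sess$sets)
    expect_length(ex_sets, 10L)
    for (set in ex_sets) {
      expect_length(set$vibrations, sm$cfg$reps_per_set)
      expect_equal(set$declared_reps, sm$cfg$reps_per_set)
      expect_true(all(diff(set$vibrations) > 0))
      expect_true(min(set$vibrations) >= set$start - 1e-9)
      expect_true(max(set$vibrations) <= set$end + 1e-9)
    }
  }
})

test_that("timestamps jitter around 100 Hz and resampling recovers the signal", {
  sm <- small_dataset()
  st <- sm$sessions[[1]]$streams[[1]]
  dt <- diff(st$time)
  expect_equal(mean(dt), 0.01, tolerance = 0.001)
  expect_gt(stats::sd(dt), 0)                     # genuinely irregular
  ## resampling a jittered noiseless stream onto the exact grid recovers the
  ## smooth oscillation to noise-dominated error
  cfg0 <- synthetic_config(n_subjects = 1, reps_per_set = 6, noise_sd = 0,
                           wander_sd = 0, null_duration = c(5, 6),
                           gap_duration = c(2, 3), seed = 13)
  s0 <- generate_dataset(cfg0)[[1]]
  set <- Filter(function(s) s$label == "E1", s0$sets)[[1]]
  rs <- resample_stream(s0$streams[[1]], 100, c(set$start + 0.2, set$end - 0.2))
  ## reference: regenerate with the same seed and compare mid-set energy
  expect_true(all(is.finite(rs$values)))
  expect_gt(stats::sd(rs$values[, 1]), 0.1)       # oscillation present
  ## linear interpolation error between ~10 ms samples of a smooth signal
  ## is far below the oscillation amplitude
  sd_diff <- stats::sd(diff(rs$values[, 1]))
  expect_lt(sd_diff, stats::sd(rs$values[, 1]))
})

test_that("class signatures are spectrally separable", {
  sm <- small_dataset()
  sess <- sm$sessions[[1]]
  cm <- assemble_channels(sess)
  sets <- Filter(function(s) s$label != null_label(), sess$sets)
  spec_of <- function(set) {
    sl <- slice_channels(cm, set$start, set$end)
    sp <- vapply(seq_len(ncol(sl$data)), function(ch) {
      p <- stats::spec.pgram(sl$data[, ch], plot = FALSE, spans = 5,
                             detrend = TRUE)
      p$spec[p$freq * 100 <= 5] / sum(p$spec[p$freq * 100 <= 5])
    }, numeric(sum(stats::spec.pgram(sl$data[, 1], plot = FALSE,
                                     spans = 5)$freq * 100 <= 5)))
    rowMeans(sp)
  }
  ## compare class pairs on a common frequency axis: use equal-length slices
  n_min <- min(vapply(sets, function(s) {
    nrow(slice_channels(cm, s$start, s$end)$data)
  }, numeric(1)))
  spec_fixed <- function(set) {
    sl <- slice_channels(cm, set$start, set$end)
    x <- sl$data[seq_len(n_min), ]
    sp <- vapply(seq_len(ncol(x)), function(ch) {
      p <- stats::spec.pgram(x[, ch], plot = FALSE, spans = 5, detrend = TRUE)
      p$spec / sum(p$spec)
    }, numeric(length(stats::spec.pgram(x[, 1], plot = FALSE,
                                        spans = 5)$spec)))
    rowMeans(sp)
  }
  specs <- lapply(sets[1:4], spec_fixed)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_gt(max(abs(specs[[i]] - specs[[j]])), 0.01)
  }
})

test_that("null segments are aperiodic in the exercise band", {
  cfg <- synthetic_config(seed = 3)
  withr::with_seed(5, {
    ns <- generate_null_segment(90, cfg, n_channels = 3)
    expect_equal(length(ns$time), 9000, tolerance = 0.01)
    for (ch in 1:3) {
      p <- stats::spec.pgram(ns$values[, ch], plot = FALSE, spans = 31,
                             detrend = TRUE)
      band <- p$freq * 100 >= 0.25 & p$freq * 100 <= 5
      expect_lt(max(p$spec[band]), 3 * stats::median(p$spec[band]))
    }
  })
  ## zero noise leaves only the smooth wander
  withr::with_seed(6, {
    cfg0 <- synthetic_config(noise_sd = 0, seed = 3)
    ns0 <- generate_null_segment(10, cfg0, n_channels = 1)
    expect_lt(stats::sd(diff(ns0$values[, 1])), 0.05)
  })
})

test_that("ground-truth table is complete and consistent", {
  sm <- small_dataset()
  gt <- ground_truth_table(sm$sessions)
  expect_equal(nrow(gt), 3 * 10)
  expect_true(all(gt$n_reps == sm$cfg$reps_per_set))
  expect_true(all(vapply(gt$rep_starts, length, integer(1)) == gt$n_reps))
  ## unconstrained sessions retain hidden starts
  cfgu <- synthetic_config(n_subjects = 1, exercises = c("E2", "E7"),
                           null_duration = c(8, 10), gap_duration = c(2, 3),
                           seed = 9)
  su <- generate_dataset(cfgu, scheme = "free10")
  gtu <- ground_truth_table(su)
  expect_equal(nrow(gtu), 2L)
  expect_true(all(gtu$n_reps == 10L))
  for (set in su[[1]]$sets) expect_length(set$vibrations, 0L)
  expect_true(all(vapply(gtu$rep_starts, length, integer(1)) == 10L))
  ## 1-2-3 scheme: three rounds per exercise
  cfg3 <- synthetic_config(n_subjects = 1, exercises = c("E2", "E7"),
                           null_duration = c(8, 10), gap_duration = c(2, 3),
                           seed = 9)
  s3 <- generate_dataset(cfg3, scheme = "one_two_three")
  gt3 <- ground_truth_table(s3)
  expect_equal(sort(gt3$n_reps), c(1L, 1L, 2L, 2L, 3L, 3L))
})
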