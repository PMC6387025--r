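## Shared fixtures: tiny hand-built sessions and small synthetic datasets.

## one stream with exact linear axes, useful for resampler exactness checks
linear_stream <- function(device = "wrist", sensor = "accelerometer",
                          t = sort(runif(50, 0, 10)), slope = c(2, -1, 0.5)) {
  t <- unique(t)
  sensor_stream(device, sensor, t, cbind(slope[1] * t, slope[2] * t,
                                         slope[3] * t))
}

## minimal valid session: one wrist accelerometer stream, one E1 set
tiny_session <- function() {
  t <- seq(0, 20, by = 0.01)
  s <- sensor_stream("wrist", "accelerometer", t,
                     cbind(sin(t), cos(t), t * 0.1))
  set <- exercise_set("E1", 2, 12, vibrations = seq(2, 11, by = 1),
                      declared_reps = 10)
  wod_session("P1", list(set), list(s))
}

## random valid session generator for round-trip property tests
random_session <- function(id = "PX", n_sets = 3, n_streams = 2) {
  pairs <- all_sensor_pairs()[seq_len(n_streams), ]
  t_end <- 10 * n_sets + 10
  streams <- lapply(seq_len(n_streams), function(i) {
    t <- sort(c(0, t_end, runif(300, 0, t_end)))
    t <- t[c(TRUE, diff(t) > 1e-6)]
    sensor_stream(pairs$device[i], pairs$sensor[i], t,
                  matrix(rnorm(3 * length(t)), ncol = 3))
  })
  sets <- lapply(seq_len(n_sets), function(i) {
    lo <- (i - 1) * 10 + 1; hi <- lo + runif(1, 3, 8)
    nv <- sample(0:4, 1)
    vib <- if (nv > 0) sort(runif(nv, lo, hi)) else numeric()
    exercise_set(sample(exercise_codes(), 1), lo, hi, vibrations = vib,
                 declared_reps = if (nv > 0) nv else NA)
  })
  wod_session(id, sets, streams)
}

## small shared synthetic dataset (3 subjects, 6 reps) cached per test run
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_subjects = 3, reps_per_set = 6,
                              null_duration = c(20, 30),
                              gap_duration = c(3, 5), seed = 7)
      cache <<- list(cfg = cfg, sessions = generate_dataset(cfg))
    }
    cache
  }
})

expect_sessions_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$participant_id, b$participant_id)
  expect_equal(a$experience, b$experience)
  expect_equal(length(a$sets), length(b$sets))
  for (i in seq_along(a$sets)) {
    expect_equal(unclass(a$sets[[i]]), unclass(b$sets[[i]]),
                 tolerance = tol, ignore_attr = TRUE)
  }
  expect_setequal(names(a$streams), names(b$streams))
  for (k in names(a$streams)) {
    expect_equal(a$streams[[k]]$time, b$streams[[k]]$time, tolerance = tol)
    expect_equal(a$streams[[k]]$values, b$streams[[k]]$values,
                 tolerance = tol, ignore_attr = TRUE)
  }
}
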