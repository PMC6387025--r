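test_that("stream and set validation reject malformed inputs", {
  expect_error(sensor_stream("wrist", "accelerometer", c(0, 1, 1),
                             matrix(0, 3, 3)), "strictly increasing")
  expect_error(sensor_stream("wrist", "accelerometer", 0:2, matrix(0, 3, 2)),
               "3 axis")
  expect_error(exercise_set("E1", 0, 10, vibrations = c(2, 11)),
               "outside set bounds")
  expect_error(exercise_set("E1", 0, 10, vibrations = c(2, 3),
                            declared_reps = 5), "equal the number")
  expect_error(exercise_set("E99", 0, 10), "invalid exercise label")
  s <- sensor_stream("wrist", "accelerometer", seq(0, 5, 0.1),
                     matrix(0, 51, 3))
  expect_error(wod_session("P", list(exercise_set("E1", 0, 3),
                                     exercise_set("E2", 2, 5)), list(s)),
               "overlap")
  expect_error(wod_session("P", list(exercise_set("E1", 0, 3)), list(s, s)),
               "duplicate")
  expect_error(wod_session("P", list(exercise_set("E1", 0, 9)), list(s)),
               "beyond stream coverage")
})

test_that("resampling is exact on linear signals and matches hand interpolation", {
  set.seed(11)
  st <- linear_stream(t = sort(runif(40, 0, 10)))
  rs <- resample_stream(st, rate = 100, grid = c(1, 9))
  expect_equal(rs$values[, 1], 2 * rs$time, tolerance = 1e-12)
  expect_equal(rs$values[, 2], -1 * rs$time, tolerance = 1e-12)
  expect_equal(diff(rs$time), rep(0.01, length(rs$time) - 1), tolerance = 1e-12)

  ## constant stream stays constant
  stc <- sensor_stream("ankle", "gyroscope", c(0, 0.4, 1.1, 2),
                       matrix(5, 4, 3))
  rsc <- resample_stream(stc, 100, c(0, 2))
  expect_true(all(rsc$values == 5))

  ## hand-computed point: t = {0, 0.013, 0.019}, x = {0, 1.3, 2.5}
  sth <- sensor_stream("wrist", "gyroscope", c(0, 0.013, 0.019),
                       cbind(c(0, 1.3, 2.5), 0, 0))
  rsh <- resample_stream(sth, 100, c(0, 0.019))
  expect_equal(unname(rsh$values[2, 1]), 0.01 / 0.013 * 1.3, tolerance = 1e-12)

  expect_error(resample_stream(st, 100, c(-5, 9)), "outside coverage")
  expect_error(resample_stream(
    sensor_stream("wrist", "orientation", 1, matrix(0, 1, 3)), 100, c(1, 1)),
    "at least 2")
})

test_that("piecewise-linear signals are reproduced exactly at grid points", {
  set.seed(3)
  for (rep in 1:5) {
    t_raw <- sort(runif(30, 0, 5))
    vals <- matrix(rnorm(90), ncol = 3)
    st <- sensor_stream("wrist", "accelerometer", t_raw, vals)
    rs <- resample_stream(st, 100, c(min(t_raw), max(t_raw)))
    expected <- vapply(1:3, function(a) {
      approx(t_raw, vals[, a], xout = rs$time)$y
    }, numeric(length(rs$time)))
    expect_equal(unname(rs$values), unname(expected), tolerance = 1e-12)
  }
})

test_that("session write/read round trip reproduces arbitrary sessions", {
  set.seed(21)
  for (i in 1:5) {
    s <- random_session(sprintf("P%d", i), n_sets = sample(1:5, 1),
                        n_streams = sample(1:6, 1))
    d <- withr::local_tempdir()
    write_session(s, d)
    expect_sessions_equal(s, read_session(d))
  }
})

test_that("session reader flags format problems and unknown sensors", {
  d <- withr::local_tempdir()
  expect_error(read_session(d), "manifest")
  s <- tiny_session()
  write_session(s, d)
  ## corrupt: vibration outside bounds
  mf <- jsonlite::read_json(file.path(d, "manifest.json"))
  mf$sets[[1]]$vibrations <- list(100)
  jsonlite::write_json(mf, file.path(d, "manifest.json"), auto_unbox = TRUE)
  expect_error(read_session(d), "outside set bounds")
  ## unknown sensor is skipped with a warning
  mf$sets[[1]]$vibrations <- list(3)
  mf$sets[[1]]$declared_reps <- 1
  mf$streams[[length(mf$streams) + 1]] <-
    list(device = "wrist", sensor = "barometer", file = "nope.csv")
  jsonlite::write_json(mf, file.path(d, "manifest.json"), auto_unbox = TRUE)
  expect_warning(s2 <- read_session(d), "unknown stream")
  expect_equal(length(s2$streams), 1L)
  ## empty-set session round trips
  d2 <- withr::local_tempdir()
  s0 <- wod_session("P0", list(), list(s$streams[[1]]))
  write_session(s0, d2)
  expect_equal(length(read_session(d2)$sets), 0L)
})

test_that("channel assembly follows the canonical order and yields 18 channels", {
  sm <- small_dataset()
  sess <- sm$sessions[[1]]
  cm <- assemble_channels(sess)
  expect_s3_class(cm, "channel_matrix")
  expect_equal(ncol(cm$data), 18L)
  expect_equal(cm$channel_order$device, rep(c("wrist", "ankle"), each = 9))
  expect_equal(cm$channel_order$sensor,
               rep(rep(c("accelerometer", "gyroscope", "orientation"),
                       each = 3), 2))
  expect_equal(cm$channel_order$axis, rep(c("x", "y", "z"), 6))

  sel <- data.frame(device = "wrist", sensor = "accelerometer")
  expect_equal(ncol(assemble_channels(sess, sel)$data), 3L)

  ## order of streams in the session does not matter
  shuffled <- sess
  shuffled$streams <- rev(sess$streams)
  cm2 <- assemble_channels(shuffled)
  expect_equal(cm$data, cm2$data)

  ## selection order does not matter either; accel precedes gyro
  sel2 <- data.frame(device = "wrist",
                     sensor = c("gyroscope", "accelerometer"))
  cm3 <- assemble_channels(sess, sel2)
  expect_equal(cm3$channel_order$sensor,
               rep(c("accelerometer", "gyroscope"), each = 3))

  bare <- wod_session("P", list(), list(sess$streams[[1]]))
  expect_error(assemble_channels(bare), "no \\(wrist, gyroscope\\)")
})

test_that("exercise config derives counting windows from vibration intervals", {
  cfg <- exercise_config(c(E1 = 1.5, E2 = 3.3333))
  expect_equal(unname(cfg$w), c(150L, 333L))
  expect_error(exercise_config(c(bad = 2)), "unknown exercise")
  expect_error(exercise_config(c(E1 = 0)), "positive")

  sm <- small_dataset()
  est <- estimate_exercise_config(sm$sessions)
  expect_setequal(names(est$t_min), exercise_codes())
  ## t_min is the minimum over subjects of each session's vibration gap
  gaps <- c()
  for (sess in sm$sessions) for (set in sess$sets) {
    if (set$label == "E3" && length(set$vibrations) > 1) {
      gaps <- c(gaps, min(diff(set$vibrations)))
    }
  }
  expect_equal(unname(est$t_min["E3"]), min(gaps))
})
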