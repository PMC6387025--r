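test_that("stride follows the overlap factor with a floor of one sample", {
  expect_equal(compute_stride(400, 0), 400L)
  expect_equal(compute_stride(400, 0.95), 20L)
  expect_equal(compute_stride(10, 0.99), 1L)
  expect_error(compute_stride(400, 1), "gamma")
  expect_error(compute_stride(400, -0.1), "gamma")
})

test_that("window count formula holds across random sizes", {
  cm0 <- channel_matrix(matrix(rnorm(1000 * 3), 1000, 3), 100, 0,
                        canonical_channel_order()[1:3, ])
  ws <- extract_windows(cm0, 400, 400)
  expect_equal(ws$starts, c(0L, 400L))
  expect_equal(length(extract_windows(cm0, 400, 20)$starts), 31L)
  expect_warning(w0 <- extract_windows(
    channel_matrix(matrix(0, 399, 3), 100, 0,
                   canonical_channel_order()[1:3, ]), 400, 10), "no windows")
  expect_equal(length(w0$starts), 0L)

  set.seed(5)
  for (i in 1:25) {
    N <- sample(50:2000, 1); W <- sample(10:min(N, 500), 1)
    stride <- sample(1:W, 1)
    cm <- channel_matrix(matrix(0, N, 3), 100, 0,
                         canonical_channel_order()[1:3, ])
    ws <- extract_windows(cm, W, stride)
    expect_equal(length(ws$starts), (N - W) %/% stride + 1L)
    expect_true(all(ws$starts + W <= N))
    ## windows are contiguous slices
    k <- sample(length(ws$starts), 1)
    expect_equal(ws$data[, , k],
                 cm$data[(ws$starts[k] + 1):(ws$starts[k] + W), ])
  }
})

test_that("recognition labels use majority set coverage with null fallback", {
  sess <- tiny_session()                    # E1 covers [2, 12] of [0, 20]
  cm <- assemble_channels(
    sess, data.frame(device = "wrist", sensor = "accelerometer"))
  ws <- extract_windows(cm, 200, 20)        # 2 s windows, 0.2 s stride
  labs <- label_recognition_windows(ws, sess)
  t_lo <- ws$t0 + ws$starts / 100
  expect_true(all(labs[t_lo >= 2 & t_lo + 2 <= 12] == "E1"))
  expect_true(all(labs[t_lo + 2 <= 2 | t_lo >= 12] == "null"))
  ## 60/40 straddling window goes to the majority set
  straddle <- which(abs(t_lo - 10.8) < 0.005)  # covers [10.8, 12.8]: 60% E1
  expect_equal(labs[straddle], "E1")
  straddle2 <- which(abs(t_lo - 11.2) < 0.005) # covers [11.2, 13.2]: 40% E1
  expect_equal(labs[straddle2], "null")
  ## exactly half coverage is not a majority
  straddle3 <- which(abs(t_lo - 11) < 0.005)
  expect_equal(labs[straddle3], "null")
})

test_that("counting labels demand full containment of the start segment", {
  cfg <- exercise_config(c(E4 = 1))          # w = 100, half = 50
  n <- 1000
  cm <- channel_matrix(matrix(0, n, 3), 100, 0,
                       canonical_channel_order()[1:3, ])
  set <- exercise_set("E4", 0, 10, vibrations = 2.5, declared_reps = 1)
  ws <- extract_windows(cm, 100, 1)
  bits <- label_counting_windows(ws, set, cfg)
  ## vibration at sample 250; segment [250, 300) fits in windows [200..250, +100)
  expect_equal(which(bits == 1L) - 1L, 200:250)
  ## [200, 300) contains it exactly; [199, 299) misses the last sample,
  ## [251, 351) starts after the vibration
  expect_equal(bits[ws$starts == 200], 1L)
  expect_equal(bits[ws$starts == 250], 1L)
  expect_equal(bits[ws$starts == 251], 0L)
  expect_equal(bits[ws$starts == 199], 0L)
  expect_error(label_counting_windows(extract_windows(cm, 99, 1), set, cfg),
               "does not match")
})

test_that("counting labels agree with a brute-force containment scan", {
  set.seed(13)
  for (i in 1:10) {
    w <- sample(c(100, 150, 250, 333), 1)
    t_min <- w / 100
    cfg <- exercise_config(setNames(t_min, "E2"))
    dur <- 30
    vib <- sort(runif(sample(3:8, 1), 1, dur - t_min - 0.5))
    vib <- vib[c(TRUE, diff(vib) > t_min)]
    set <- exercise_set("E2", 0, dur, vibrations = vib,
                        declared_reps = length(vib))
    cm <- channel_matrix(matrix(0, dur * 100, 3), 100, 0,
                         canonical_channel_order()[1:3, ])
    stride <- sample(1:10, 1)
    ws <- extract_windows(cm, w, stride)
    bits <- label_counting_windows(ws, set, cfg)
    v_samp <- round(vib * 100)
    expect_equal(bits, oracle_counting_bits(ws$starts, w, v_samp, w %/% 2))
    ## each isolated, interior vibration yields about (w - floor(w/2))/stride
    ## consecutive 1-windows (exact count depends on grid alignment)
    if (all(diff(v_samp) > w + w %/% 2) &&
        min(v_samp) + w %/% 2 - w >= 0 && max(v_samp) <= max(ws$starts)) {
      on <- rle(bits)
      k0 <- (w - w %/% 2) %/% stride
      expect_true(all(on$lengths[on$values == 1] %in% c(k0, k0 + 1L)))
      expect_equal(sum(on$values == 1), length(v_samp))
    }
  }
})

test_that("training batches are uniform i.i.d. draws with replacement", {
  expect_error(sample_training_batch(0), "empty")
  set.seed(1)
  expect_equal(length(sample_training_batch(1, 30)), 30L)
  expect_true(all(sample_training_batch(1, 30) == 1L))
  set.seed(99); b1 <- sample_training_batch(50, 30)
  set.seed(99); b2 <- sample_training_batch(50, 30)
  expect_identical(b1, b2)
  set.seed(7)
  draws <- sample_training_batch(4, 1e4)
  expect_true(all(abs(tabulate(draws, 4) / 1e4 - 0.25) < 0.02))
})
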