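test_that("average reference recovers the recording reference exactly", {
  # two channels vs A1 with a single sample (3, 0): the mean over the three
  # true signals {3, 0, 0} is 1, so the result is (2, -1) and A1 = -1
  rec <- raw_recording(matrix(c(3, 0), 2, 1), 500,
                       channel_labels = c("c1", "c2"), reference_label = "A1")
  out <- average_reference(rec)
  expect_equal(out$channel_labels, c("c1", "c2", "A1"))
  expect_equal(as.vector(out$data), c(2, -1, -1))
  expect_equal(sum(out$data), 0)

  zero <- average_reference(raw_recording(matrix(0, 2, 5), 500,
                                          channel_labels = c("c1", "c2"),
                                          reference_label = "A1"))
  expect_true(all(zero$data == 0))
})

test_that("after average referencing, scalp channels sum to zero per sample", {
  set.seed(21)
  rec <- raw_recording(matrix(rnorm(6 * 50, sd = 20), 6, 50), 500,
                       channel_labels = c("a", "b", "c", "d", "e", "IO1"),
                       reference_label = "A1")
  out <- average_reference(rec)
  scalp <- out$channel_types == "scalp"
  expect_lt(max(abs(colMeans(out$data[scalp, ]))), 1e-9)
  # the EOG channel is re-expressed but never enters the average
  expect_equal(sum(scalp), 6)
})

test_that("average reference validates its reference label", {
  rec <- raw_recording(matrix(0, 2, 5), 500, channel_labels = c("a", "b"))
  expect_error(average_reference(rec), "reference_label")
  rec2 <- raw_recording(matrix(0, 2, 5), 500, channel_labels = c("a", "A1"),
                        reference_label = "A1")
  expect_error(average_reference(rec2), "already present")
})

test_that("the band-pass filter has the designed pass- and stop-band behavior", {
  fs <- 500
  t <- seq_len(10 * fs) / fs
  central <- seq(fs, 9 * fs)  # central 80 percent
  cfg <- preprocess_config()
  mk <- function(x) raw_recording(matrix(x, 1, length(x)), fs,
                                  channel_labels = "Cz")
  # 10 Hz is mid-passband: unit amplitude preserved within 5 percent
  out10 <- bandpass_filter(mk(sin(2 * pi * 10 * t)), cfg)
  expect_lt(abs(max(abs(out10$data[1, central])) - 1), 0.05)
  # 60 Hz sits in the stop band of the 40 Hz low-pass
  out60 <- bandpass_filter(mk(sin(2 * pi * 60 * t)), cfg)
  expect_lt(max(abs(out60$data[1, central])), 0.3)
  # DC is removed by the 0.5 Hz high-pass
  outdc <- bandpass_filter(mk(rep(100, length(t))), cfg)
  expect_lt(abs(mean(outdc$data[1, central])), 1)
})

test_that("the filter is zero phase: a symmetric pulse keeps its peak", {
  fs <- 500
  n <- 4 * fs
  x <- exp(-((seq_len(n) - n / 2)^2) / (2 * 15^2))
  rec <- raw_recording(matrix(x, 1, n), fs, channel_labels = "Cz")
  out <- bandpass_filter(rec, preprocess_config())
  expect_lte(abs(which.max(out$data[1, ]) - which.max(x)), 1)
})

test_that("epoching honors the half-open window and drops edge events", {
  fs <- 500
  rec <- raw_recording(matrix(rnorm(2 * 3000), 2, 3000), fs,
                       channel_labels = c("a", "b"),
                       events = tibble::tibble(
                         sample_index = c(10L, 500L, 1500L),
                         code = c("S  1", "S  1", "S  1")))
  cfg <- preprocess_config()
  expect_warning(ep <- epoch(rec, "S  1", cfg), "edge")
  expect_equal(dim(ep$data)[2], 500L)        # 1 s at 500 Hz, half-open
  expect_equal(dim(ep$data)[3], 2L)          # event at sample 10 dropped
  expect_equal(attr(ep, "dropped_events"), 1L)
  expect_equal(ep$time_ms[1], -200)
  expect_equal(ep$time_ms[length(ep$time_ms)], 798)
  expect_true(0 %in% ep$time_ms)
  # epochs follow marker order and copy the right samples
  expect_equal(ep$data[, , 1], rec$data[, 400:899])
  expect_error(epoch(rec, "S 99", cfg), "S 99")
})

test_that("baseline correction zeroes the prestimulus mean and is idempotent", {
  fs <- 500
  cfg <- preprocess_config(epoch_window_ms = c(-200, 800))
  time_ms <- seq(-200, 798, by = 2)
  const <- epoch_set(array(7, c(2, 500, 3)), time_ms, fs,
                     channel_labels = c("a", "b"))
  expect_true(all(baseline_correct(const, cfg)$data == 0))

  ramp <- epoch_set(array(rep(time_ms, each = 2), c(2, 500, 1)), time_ms, fs,
                    channel_labels = c("a", "b"))
  out <- baseline_correct(ramp, cfg)
  bidx <- which(time_ms < 0)
  expect_lt(max(abs(apply(out$data[, bidx, , drop = FALSE], c(1, 3), mean))),
            1e-9)
  # every sample is shifted by minus the baseline mean
  expect_equal(out$data[1, , 1], time_ms - mean(time_ms[bidx]))
  twice <- baseline_correct(out, cfg)
  expect_equal(twice$data, out$data)
})

test_that("artifact flags implement the amplitude and gradient thresholds", {
  fs <- 500
  time_ms <- seq(-200, 798, by = 2)
  mk <- function(x) epoch_set(x, time_ms, fs,
                              channel_labels = paste0("ch", seq_len(dim(x)[1])))
  cfg <- preprocess_config()

  spike <- array(0, c(2, 500, 1)); spike[2, 300, 1] <- 151
  expect_false(detect_artifacts(mk(spike), cfg))
  # gradient-free constants isolate the amplitude rule: the bound is exclusive
  expect_false(detect_artifacts(mk(array(151, c(2, 500, 1))), cfg))
  expect_true(detect_artifacts(mk(array(150, c(2, 500, 1))), cfg))

  step <- array(0, c(1, 500, 1)); step[1, 250:500, 1] <- 51
  expect_false(detect_artifacts(mk(step), cfg))
  step50 <- array(0, c(1, 500, 1)); step50[1, 250:500, 1] <- 50
  expect_true(detect_artifacts(mk(step50), cfg))

  expect_true(detect_artifacts(mk(array(0, c(2, 500, 1))), cfg))
})

test_that("artifact detection equals a brute-force per-sample scan", {
  set.seed(33)
  cfg <- preprocess_config()
  for (rep in 1:20) {
    x <- array(rnorm(3 * 40 * 5, sd = sample(c(30, 60, 90), 1)),
               c(3, 40, 5))
    ep <- epoch_set(x, (0:39) * 2, 500, channel_labels = c("a", "b", "c"))
    oracle <- vapply(1:5, function(tr) {
      bad <- FALSE
      for (ch in 1:3) {
        for (s in 1:40) if (abs(x[ch, s, tr]) > 150) bad <- TRUE
        for (s in 1:39) if (abs(x[ch, s + 1, tr] - x[ch, s, tr]) > 50) bad <- TRUE
      }
      !bad
    }, logical(1))
    expect_identical(detect_artifacts(ep, cfg), oracle)
  }
})

test_that("config invariants are enforced", {
  expect_error(preprocess_config(highpass_hz = 45, lowpass_hz = 40), "below")
  expect_error(preprocess_config(baseline_window_ms = c(-300, 0)), "inside")
  expect_error(preprocess_config(abs_thresh_uv = -1), "> 0")
})
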