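make_epochs <- function(pid, n_trials, n_ch = 2, n_samp = 6, seed = 1) {
  set.seed(seed)
  epoch_set(array(rnorm(n_ch * n_samp * n_trials), c(n_ch, n_samp, n_trials)),
            (0:(n_samp - 1)) * 2, 500,
            channel_labels = paste0("ch", seq_len(n_ch)),
            participant_id = pid)
}

test_that("build_store concatenates participants in order, matched by position", {
  eps <- list(make_epochs("P01", 3, seed = 1), make_epochs("P02", 3, seed = 2))
  beh <- list(tibble::tibble(trial_index = 1:3, rt_ms = c(400, 500, 600)),
              tibble::tibble(trial_index = 1:3, rt_ms = c(700, 800, 900)))
  store <- build_store(eps, beh)
  expect_equal(n_trials(store), 6L)
  expect_equal(store$meta$participant_id, rep(c("P01", "P02"), each = 3))
  expect_equal(store$meta$rt_ms, c(400, 500, 600, 700, 800, 900))
  expect_equal(store$amplitudes[, , 4], eps[[2]]$data[, , 1])
})

test_that("count and axis mismatches are hard errors naming the participant", {
  eps <- list(make_epochs("P01", 3), make_epochs("P02", 3))
  beh_bad <- list(tibble::tibble(trial_index = 1:3),
                  tibble::tibble(trial_index = 1:4))
  expect_error(build_store(eps, beh_bad), "P02.*4.*3")
  eps2 <- list(make_epochs("P01", 3), make_epochs("P02", 3, n_ch = 3))
  expect_error(build_store(eps2, list(tibble::tibble(trial_index = 1:3),
                                      tibble::tibble(trial_index = 1:3))),
               "channel")
})

test_that("subset_trials filters by metadata predicates and composes", {
  store <- random_store(n_trials = 10, seed = 6)
  store$meta$response <- factor(c(rep("hit", 7), rep("error", 3)),
                                c("hit", "error", "miss"))
  hits <- subset_trials(store, response == "hit")
  expect_equal(n_trials(hits), 7L)
  expect_identical(subset_trials(store, rep(TRUE, 10))$amplitudes,
                   store$amplitudes)
  ab <- subset_trials(subset_trials(store, response == "hit"), rt_ms < 600)
  both <- subset_trials(store, response == "hit" & rt_ms < 600)
  expect_identical(ab$amplitudes, both$amplitudes)
  expect_equal(as.data.frame(ab$meta), as.data.frame(both$meta))
  expect_error(subset_trials(store, no_such_column == 1), "no_such_column")
})

test_that("analysis filters implement the staged exclusion rules", {
  # 12 trials: 2 on top/bottom, 1 miss, 2 errors, the rest usable hits
  meta <- tibble::tibble(
    participant_id = "P01", trial_index = 1:12,
    deviant_position = factor(c("top", "bottom", rep(c("left", "right"), 5)),
                              c("left", "right", "top", "bottom")),
    response = factor(c("hit", "hit", "miss", "error", "error",
                        rep("hit", 7)), c("hit", "error", "miss")))
  store <- make_store(array(0, c(2, 4, 12)), meta)
  expect_equal(n_trials(apply_analysis_filters(store, "accuracy")), 9L)
  expect_equal(n_trials(apply_analysis_filters(store, "rt_erp")), 7L)
  # conjunction: stage filters are order-independent
  a <- apply_analysis_filters(store, "rt_erp")
  b <- subset_trials(
    subset_trials(store, !(deviant_position %in% c("top", "bottom"))),
    response == "hit" & eeg_valid)
  expect_equal(as.data.frame(a$meta), as.data.frame(b$meta))
  # a store with nothing to exclude passes through unchanged
  clean <- subset_trials(store, response == "hit" &
                           deviant_position %in% c("left", "right"))
  expect_equal(n_trials(apply_analysis_filters(clean, "rt_erp")),
               n_trials(clean))
})

test_that("mean_amplitude equals a brute-force double loop and masks invalid trials", {
  store <- random_store(n_ch = 4, n_samp = 12, n_trials = 10, seed = 9)
  store$meta$eeg_valid <- c(rep(TRUE, 8), FALSE, FALSE)
  chans <- c("ch2", "ch4")
  window <- c(6, 18)  # samples 4..9 on the 2 ms grid
  got <- mean_amplitude(store, chans, window)
  sidx <- which(store$time_ms >= 6 & store$time_ms < 18)
  for (tr in 1:8) {
    acc <- c()
    for (ch in match(chans, store$channel_labels))
      for (s in sidx) acc <- c(acc, store$amplitudes[ch, s, tr])
    expect_equal(got[tr], mean(acc))
  }
  expect_true(all(is.nan(got[9:10])))
  # single channel, single sample window returns that sample
  one <- mean_amplitude(store, "ch1", c(0, 2))
  expect_equal(one[1], unname(store$amplitudes[1, 1, 1]))
  # constant epochs
  const <- make_store(array(-3, c(2, 4, 5)),
                      tibble::tibble(participant_id = "P01", trial_index = 1:5))
  expect_equal(mean_amplitude(const, c("ch1", "ch2"), c(0, 8)), rep(-3, 5))
  expect_error(mean_amplitude(store, "nope", window), "nope")
})

test_that("export_long keeps exactly the valid trials", {
  store <- random_store(n_ch = 2, n_samp = 8, n_trials = 12, seed = 10)
  store$meta$eeg_valid <- c(rep(TRUE, 10), FALSE, FALSE)
  tab <- export_long(store, "ch1", c(0, 16), amplitude_col = "amp")
  expect_equal(nrow(tab), 10L)
  # full-epoch window on one channel equals that channel's per-trial mean
  expect_equal(tab$amp, apply(store$amplitudes[1, , 1:10], 2, mean))
  p <- withr::local_tempfile(fileext = ".csv")
  export_long(store, "ch1", c(0, 16), path = p)
  expect_equal(nrow(read.csv(p)), 10L)
})

test_that("store invariants are enforced at construction", {
  meta <- tibble::tibble(participant_id = "P01", trial_index = c(1L, 3L, 2L))
  expect_error(make_store(array(0, c(2, 4, 3)), meta), "strictly increasing")
  meta2 <- tibble::tibble(participant_id = "P01", trial_index = 1:2)
  expect_error(make_store(array(0, c(2, 4, 3)), meta2), "2 rows")
})
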