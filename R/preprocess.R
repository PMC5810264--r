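#' Preprocessing configuration
#'
#' Defaults are the conventional single-trial ERP settings: 0.5–40 Hz
#' zero-phase band-pass, epochs from −200 to 800 ms around stimulus onset
#' (half-open window), baseline −200 to 0 ms, and artifact thresholds of
#' ±150 uV absolute amplitude / 50 uV sample-to-sample gradient.
#'
#' @param highpass_hz High-pass cutoff (Hz).
#' @param lowpass_hz Low-pass cutoff (Hz); must exceed `highpass_hz`.
#' @param epoch_window_ms Half-open epoch window `c(start, end)` in ms
#'   relative to the event; the sample at t = 0 is the first post-stimulus
#'   sample.
#' @param baseline_window_ms Half-open baseline window, inside the epoch.
#' @param abs_thresh_uv Absolute amplitude threshold (uV).
#' @param grad_thresh_uv Max allowed |difference| between consecutive
#'   samples (uV).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(highpass_hz = 0.5, lowpass_hz = 40,
                              epoch_window_ms = c(-200, 800),
                              baseline_window_ms = c(-200, 0),
                              abs_thresh_uv = 150, grad_thresh_uv = 50) {
  stopifnot_scalar_number(highpass_hz, "highpass_hz", positive = TRUE)
  stopifnot_scalar_number(lowpass_hz, "lowpass_hz", positive = TRUE)
  if (highpass_hz >= lowpass_hz)
    abort("highpass_hz must be below lowpass_hz.")
  if (length(epoch_window_ms) != 2L || epoch_window_ms[1] >= epoch_window_ms[2])
    abort("epoch_window_ms must be c(start, end) with start < end.")
  if (length(baseline_window_ms) != 2L ||
      baseline_window_ms[1] >= baseline_window_ms[2])
    abort("baseline_window_ms must be c(start, end) with start < end.")
  if (baseline_window_ms[1] < epoch_window_ms[1] ||
      baseline_window_ms[2] > epoch_window_ms[2])
    abort("baseline window must lie inside the epoch window.")
  stopifnot_scalar_number(abs_thresh_uv, "abs_thresh_uv", positive = TRUE)
  stopifnot_scalar_number(grad_thresh_uv, "grad_thresh_uv", positive = TRUE)
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 epoch_window_ms = as.numeric(epoch_window_ms),
                 baseline_window_ms = as.numeric(baseline_window_ms),
                 abs_thresh_uv = abs_thresh_uv,
                 grad_thresh_uv = grad_thresh_uv),
            class = "preprocess_config")
}

#' Re-reference to the common average and recover the reference channel
#'
#' Re-expresses every channel relative to the mean of all scalp channels
#' (the recovered recording reference included, whose original value is 0 by
#' definition) and appends the recovered reference as a data channel. After
#' this step the per-sample mean over all scalp channels is exactly zero.
#'
#' With n recorded scalp channels the new value of channel i is
#' `x_i - sum(x_scalp) / (n + 1)` and the recovered reference equals
#' `-sum(x_scalp) / (n + 1)`.
#'
#' @param rec A [raw_recording()] whose `reference_label` names the
#'   recording reference; it must not already be a data channel.
#' @return A [raw_recording()] with one extra (scalp) channel and
#'   `reference_label` unchanged.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  if (is.null(rec$reference_label))
    abort("recording has no reference_label; cannot recover the reference.")
  if (rec$reference_label %in% rec$channel_labels)
    abort(sprintf("reference channel %s is already present as a data channel.",
                  rec$reference_label))
  scalp <- rec$channel_types == "scalp"
  if (!any(scalp)) abort("no scalp channels to average over.")
  n <- sum(scalp)
  m <- colSums(rec$data[scalp, , drop = FALSE]) / (n + 1)
  data <- sweep(rec$data, 2L, m, "-")
  data <- rbind(data, -m)
  raw_recording(data, rec$sampling_rate,
                channel_labels = c(rec$channel_labels, rec$reference_label),
                reference_label = rec$reference_label,
                events = rec$events,
                channel_types = c(rec$channel_types, "scalp"),
                meta = c(rec$meta, list(referencing = "average")))
}

#' Zero-phase band-pass filter
#'
#' Cascaded 4th-order Butterworth high-pass and low-pass sections, each
#' applied forward and backward (`signal::filtfilt`), so the net filter has
#' zero phase shift and component latencies are preserved.
#'
#' @param rec A [raw_recording()].
#' @param cfg A [preprocess_config()]; the cutoffs must lie below the
#'   Nyquist frequency.
#' @return Filtered [raw_recording()] of identical shape.
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(cfg, "preprocess_config"))
  nyq <- rec$sampling_rate / 2
  if (cfg$lowpass_hz >= nyq)
    abort(sprintf("lowpass_hz (%g) must be below Nyquist (%g Hz).",
                  cfg$lowpass_hz, nyq))
  if (ncol(rec$data) <= 3 * 8)  # 3x the order of the cascaded sections
    abort("recording too short to filter stably.")
  hp <- signal::butter(4, cfg$highpass_hz / nyq, type = "high")
  lp <- signal::butter(4, cfg$lowpass_hz / nyq, type = "low")
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    x <- signal::filtfilt(hp, rec$data[i, ])
    out$data[i, ] <- signal::filtfilt(lp, x)
  }
  out$meta <- c(out$meta,
                list(filter = sprintf("butterworth4 zero-phase %g-%g Hz",
                                      cfg$highpass_hz, cfg$lowpass_hz)))
  out
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' One epoch per event whose marker code matches `codes`, using the
#' half-open window `cfg$epoch_window_ms`: at 500 Hz, \[−200, 800) ms gives
#' exactly 500 samples, with the event sample at t = 0. Events too close to
#' the recording edge are dropped with a warning that records their indices
#' (no zero-padding: padding would fabricate data).
#'
#' @param rec A [raw_recording()].
#' @param codes Marker codes to epoch around.
#' @param cfg A [preprocess_config()].
#' @return An [epoch_set()]; attribute `dropped_events` holds the row
#'   indices (into `rec$events`) of edge-dropped events.
#' @export
epoch <- function(rec, codes, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(cfg, "preprocess_config"))
  hits <- which(rec$events$code %in% codes)
  if (length(hits) == 0L)
    abort(sprintf("no events with code(s): %s", paste(codes, collapse = ", ")))
  fs <- rec$sampling_rate
  off0 <- ceiling(cfg$epoch_window_ms[1] * fs / 1000)
  n_samp <- round((cfg$epoch_window_ms[2] - cfg$epoch_window_ms[1]) * fs / 1000)
  offsets <- off0 + seq_len(n_samp) - 1L
  time_ms <- offsets * 1000 / fs

  onsets <- rec$events$sample_index[hits]
  ok <- onsets + off0 >= 1L & onsets + offsets[n_samp] <= ncol(rec$data)
  if (any(!ok)) {
    warn(sprintf("dropped %d event(s) too close to the recording edge (event row(s) %s).",
                 sum(!ok), paste(hits[!ok], collapse = ", ")))
  }
  kept <- hits[ok]
  if (length(kept) == 0L)
    abort("all matching events fall too close to the recording edge.")
  data <- array(0, dim = c(nrow(rec$data), n_samp, length(kept)))
  for (j in seq_along(kept)) {
    s0 <- rec$events$sample_index[kept[j]]
    data[, , j] <- rec$data[, s0 + offsets, drop = FALSE]
  }
  ep <- epoch_set(data, time_ms, fs, channel_labels = rec$channel_labels,
                  event_codes = rec$events$code[kept],
                  participant_id = rec$meta$participant_id %||% NA_character_)
  attr(ep, "dropped_events") <- hits[!ok]
  ep
}

#' Baseline-correct epochs to the prestimulus interval
#'
#' Subtracts, per trial and channel, the mean over the baseline window, so
#' the corrected baseline mean is exactly zero. Idempotent.
#'
#' @param ep An [epoch_set()].
#' @param cfg A [preprocess_config()]; `baseline_window_ms` must lie inside
#'   the epoch.
#' @return Baseline-corrected [epoch_set()].
#' @export
baseline_correct <- function(ep, cfg = preprocess_config()) {
  stopifnot(inherits(ep, "epoch_set"), inherits(cfg, "preprocess_config"))
  bw <- cfg$baseline_window_ms
  if (bw[1] < min(ep$time_ms) || bw[2] > max(ep$time_ms) + 1000 / ep$sampling_rate)
    abort("baseline window lies outside the epoch.")
  bidx <- window_index(ep$time_ms, bw)
  d <- dim(ep$data)
  bl <- apply(ep$data[, bidx, , drop = FALSE], c(1, 3), mean)  # ch x trial
  out <- ep
  out$data <- ep$data - aperm(array(bl, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  out
}

#' Flag artifact trials by amplitude and gradient thresholds
#'
#' A trial is invalid iff any channel exceeds `abs_thresh_uv` in absolute
#' amplitude at any sample, or any consecutive-sample difference exceeds
#' `grad_thresh_uv` in absolute value. Flags only — no data are removed, so
#' the store keeps the original recording order and behavioral analyses can
#' still use the full trial count.
#'
#' @param ep An [epoch_set()].
#' @param cfg A [preprocess_config()].
#' @return Logical vector of per-trial validity (`TRUE` = clean).
#' @export
detect_artifacts <- function(ep, cfg = preprocess_config()) {
  stopifnot(inherits(ep, "epoch_set"), inherits(cfg, "preprocess_config"))
  nt <- dim(ep$data)[3]
  vapply(seq_len(nt), function(j) {
    x <- ep$data[, , j, drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = dim(ep$data)[1])
    if (any(abs(x) > cfg$abs_thresh_uv)) return(FALSE)
    if (ncol(x) > 1 &&
        any(abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]) >
            cfg$grad_thresh_uv)) return(FALSE)
    TRUE
  }, logical(1))
}

#' Run the full deterministic preprocessing chain
#'
#' Fixed order: average reference (with reference recovery) → band-pass
#' filter → epoching → baseline correction → artifact flagging. Ocular
#' correction is intentionally absent (out of scope); apply your own between
#' referencing and filtering if needed.
#'
#' @param rec A [raw_recording()].
#' @param codes Event codes to epoch around.
#' @param cfg A [preprocess_config()].
#' @return An [epoch_set()] with `valid` flags set.
#' @export
preprocess <- function(rec, codes, cfg = preprocess_config()) {
  rec <- average_reference(rec)
  rec <- bandpass_filter(rec, cfg)
  ep <- epoch(rec, codes, cfg)
  ep <- baseline_correct(ep, cfg)
  ep$valid <- detect_artifacts(ep, cfg)
  inform(sprintf("preprocess: %d epochs, %d invalidated by artifact thresholds.",
                 n_trials(ep), sum(!ep$valid)))
  ep
}
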