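#' Continuous multichannel EEG recording
#'
#' Container for a continuous recording: a channels-by-samples amplitude
#' matrix in microvolts, the sampling rate, ordered channel labels, the
#' label of the recording reference (if known), and event markers.
#'
#' @param data Numeric matrix, channels x samples, amplitudes in uV.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique channel names, one per
#'   row of `data`. Defaults to `rownames(data)`.
#' @param reference_label Name of the recording reference electrode (e.g.
#'   `"A1"`), or `NULL` if unknown. The reference itself carries no data
#'   row until [average_reference()] recovers it.
#' @param events Tibble/data.frame with columns `sample_index` (1-based,
#'   within the recording) and `code` (marker string). May have zero rows.
#' @param channel_types Character vector, `"scalp"` or `"eog"` (or other
#'   non-scalp types) per channel. Defaults to `"scalp"` everywhere except
#'   labels starting with "IO", "EOG", "HEOG", "VEOG".
#' @param meta Free-form provenance list.
#'
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, sampling_rate, channel_labels = rownames(data),
                          reference_label = NULL,
                          events = tibble(sample_index = integer(), code = character()),
                          channel_types = NULL, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    abort("`data` must be a numeric channels x samples matrix.")
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (is.null(channel_labels))
    abort("`channel_labels` must be supplied (or set as rownames of `data`).")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    abort("length(channel_labels) must equal nrow(data).")
  if (anyDuplicated(channel_labels))
    abort(sprintf("channel labels must be unique; duplicated: %s",
                  paste(unique(channel_labels[duplicated(channel_labels)]),
                        collapse = ", ")))
  events <- as_tibble(events)
  if (!all(c("sample_index", "code") %in% names(events)))
    abort("`events` needs columns `sample_index` and `code`.")
  if (nrow(events) > 0 &&
      (any(events$sample_index < 1L) || any(events$sample_index > ncol(data))))
    abort("event sample_index out of range [1, n_samples].")
  if (is.null(channel_types)) {
    channel_types <- ifelse(grepl("^(IO|EOG|HEOG|VEOG)", channel_labels),
                            "eog", "scalp")
  }
  if (length(channel_types) != nrow(data))
    abort("length(channel_types) must equal nrow(data).")
  rownames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_labels = channel_labels, reference_label = reference_label,
         events = events, channel_types = channel_types, meta = meta),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  cat(sprintf("  reference: %s | events: %d | scalp channels: %d\n",
              x$reference_label %||% "<unknown>", nrow(x$events),
              sum(x$channel_types == "scalp")))
  invisible(x)
}

#' Set of fixed-length epochs for one participant
#'
#' @param data Numeric array channels x samples x trials (uV).
#' @param time_ms Per-sample times in ms relative to event onset; strictly
#'   increasing with uniform step `1000 / sampling_rate`.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Unique channel names.
#' @param event_codes Character vector, one marker code per trial.
#' @param participant_id Scalar identifier.
#' @param valid Logical per-trial validity flags (default all `TRUE`);
#'   see [detect_artifacts()].
#'
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, sampling_rate,
                      channel_labels = rownames(data),
                      event_codes = rep(NA_character_, dim(data)[3]),
                      participant_id = NA_character_,
                      valid = rep(TRUE, dim(data)[3])) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3-D array: channels x samples x trials.")
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (length(time_ms) != dim(data)[2])
    abort("length(time_ms) must equal the sample dimension of `data`.")
  step <- 1000 / sampling_rate
  if (length(time_ms) > 1 &&
      max(abs(diff(time_ms) - step)) > 1e-9)
    abort("`time_ms` must increase uniformly by 1000/sampling_rate.")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != dim(data)[1] || anyDuplicated(channel_labels))
    abort("`channel_labels` must be unique, one per channel row.")
  if (length(event_codes) != dim(data)[3])
    abort("`event_codes` must have one entry per trial.")
  if (length(valid) != dim(data)[3] || !is.logical(valid))
    abort("`valid` must be a logical vector with one flag per trial.")
  dimnames(data) <- list(channel_labels, NULL, NULL)
  structure(
    list(data = data, time_ms = as.numeric(time_ms),
         sampling_rate = sampling_rate, channel_labels = channel_labels,
         event_codes = as.character(event_codes),
         participant_id = participant_id, valid = valid),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> participant %s: %d channels x %d samples x %d trials\n",
              as.character(x$participant_id), d[1], d[2], d[3]))
  cat(sprintf("  time %g..%g ms @ %g Hz | valid trials: %d/%d\n",
              min(x$time_ms), max(x$time_ms), x$sampling_rate,
              sum(x$valid), d[3]))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param x An `epoch_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(x) UseMethod("n_trials")

#' @export
n_trials.epoch_set <- function(x) dim(x$data)[3]
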