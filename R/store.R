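#' The 3-D trial store
#'
#' The central data structure of the pipeline: one amplitude array holding
#' every trial of every participant (channels x samples x trials, in uV,
#' participants concatenated in input order, trials in original recording
#' order within participant) plus a metadata tibble with exactly one row per
#' trial. Because EEG and behavior are aligned by (participant, ordinal
#' position in recording), any behavioral column can be used to subset the
#' EEG and vice versa.
#'
#' @param amplitudes Numeric 3-D array channels x samples x trials (uV).
#' @param time_ms Shared per-sample time axis (ms relative to onset).
#' @param channel_labels Unique channel names, one per array row.
#' @param meta Tibble with one row per trial. Must contain `participant_id`
#'   and `trial_index` (position in recording order, strictly increasing
#'   within participant). An `eeg_valid` logical column is added (all `TRUE`)
#'   if absent.
#' @param sampling_rate Sampling rate in Hz.
#'
#' @return An object of class `trial_store`.
#' @export
trial_store <- function(amplitudes, time_ms, channel_labels, meta,
                        sampling_rate = 1000 / diff(time_ms[1:2])) {
  if (!is.array(amplitudes) || length(dim(amplitudes)) != 3L)
    abort("`amplitudes` must be channels x samples x trials.")
  d <- dim(amplitudes)
  meta <- as_tibble(meta)
  if (nrow(meta) != d[3])
    abort(sprintf("meta has %d rows but the array holds %d trials.",
                  nrow(meta), d[3]))
  if (length(time_ms) != d[2])
    abort("length(time_ms) must equal the sample dimension.")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != d[1] || anyDuplicated(channel_labels))
    abort("`channel_labels` must be unique, one per channel.")
  if (!all(c("participant_id", "trial_index") %in% names(meta)))
    abort("meta must contain `participant_id` and `trial_index` columns.")
  if (!"eeg_valid" %in% names(meta)) meta$eeg_valid <- TRUE
  bad <- meta |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$trial_index, strictly = TRUE)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0)
    abort(sprintf("trial_index must be strictly increasing within participant; violated for: %s",
                  paste(bad$participant_id, collapse = ", ")))
  dimnames(amplitudes) <- list(channel_labels, NULL, NULL)
  structure(
    list(amplitudes = amplitudes, time_ms = as.numeric(time_ms),
         channel_labels = channel_labels, meta = meta,
         sampling_rate = sampling_rate),
    class = "trial_store")
}

#' @export
print.trial_store <- function(x, ...) {
  d <- dim(x$amplitudes)
  cat(sprintf("<trial_store> %d channels x %d samples x %d trials (%d participants)\n",
              d[1], d[2], d[3], dplyr::n_distinct(x$meta$participant_id)))
  cat(sprintf("  time %g..%g ms @ %g Hz | eeg-valid trials: %d/%d\n",
              min(x$time_ms), max(x$time_ms), x$sampling_rate,
              sum(x$meta$eeg_valid), d[3]))
  cat(sprintf("  meta columns: %s\n", paste(names(x$meta), collapse = ", ")))
  invisible(x)
}

#' Number of trials in a store
#' @export
n_trials.trial_store <- function(x) dim(x$amplitudes)[3]

#' Combine per-participant epochs and behavior into one trial store
#'
#' Matches EEG epochs with behavioral rows strictly by (participant, ordinal
#' position in recording order) — never by trial content — and refuses to
#' align anything whose counts disagree.
#'
#' @param epochs_by_participant List of [epoch_set()] objects (one per
#'   participant, identical channel sets and time axes).
#' @param behavior_by_participant List of per-participant behavioral tables,
#'   same length/order; each must have exactly one row per epoch, in
#'   recording order, including a `trial_index` column.
#' @return A [trial_store()]. The `eeg_valid` column is taken from each
#'   epoch set's validity flags.
#' @export
build_store <- function(epochs_by_participant, behavior_by_participant) {
  if (length(epochs_by_participant) != length(behavior_by_participant))
    abort("epoch and behavior lists must have the same length.")
  if (length(epochs_by_participant) == 0L)
    abort("need at least one participant.")
  ref <- epochs_by_participant[[1]]
  for (i in seq_along(epochs_by_participant)) {
    ep <- epochs_by_participant[[i]]
    beh <- behavior_by_participant[[i]]
    pid <- as.character(ep$participant_id)
    if (!identical(ep$channel_labels, ref$channel_labels))
      abort(sprintf("participant %s: channel set differs from the first participant's.", pid))
    if (!isTRUE(all.equal(ep$time_ms, ref$time_ms)))
      abort(sprintf("participant %s: time axis differs from the first participant's.", pid))
    if (nrow(beh) != n_trials(ep))
      abort(sprintf("participant %s: %d behavioral rows but %d epochs; refusing to align.",
                    pid, nrow(beh), n_trials(ep)))
  }
  metas <- purrr::map2(epochs_by_participant, behavior_by_participant,
                       function(ep, beh) {
                         beh <- as_tibble(beh)
                         beh$participant_id <- as.character(ep$participant_id)
                         if (!"trial_index" %in% names(beh))
                           beh$trial_index <- seq_len(nrow(beh))
                         beh$eeg_valid <- ep$valid
                         beh
                       })
  meta <- dplyr::bind_rows(metas)
  amplitudes <- array(
    unlist(lapply(epochs_by_participant, function(ep) ep$data),
           use.names = FALSE),
    dim = c(dim(ref$data)[1:2], nrow(meta)))
  trial_store(amplitudes, ref$time_ms, ref$channel_labels, meta,
              sampling_rate = ref$sampling_rate)
}

#' Subset a trial store by a predicate over its metadata
#'
#' @param store A [trial_store()].
#' @param predicate Unquoted logical expression over metadata columns,
#'   evaluated tidyverse-style (e.g. `response == "hit" & rt_ms < 1000`).
#' @return A [trial_store()] with the matching trials, order preserved.
#'   Subsetting composes: `subset_trials(subset_trials(s, A), B)` equals
#'   `subset_trials(s, A & B)`.
#' @export
subset_trials <- function(store, predicate) {
  stopifnot(inherits(store, "trial_store"))
  q <- enquo(predicate)
  keep <- tryCatch(
    eval_tidy(q, data = store$meta),
    error = function(e)
      abort(sprintf("predicate could not be evaluated over the metadata columns (%s): %s",
                    paste(names(store$meta), collapse = ", "),
                    conditionMessage(e))))
  if (!is.logical(keep) || length(keep) != nrow(store$meta))
    abort("predicate must evaluate to one logical per trial.")
  keep[is.na(keep)] <- FALSE
  store_take(store, which(keep))
}

# Positional subset shared by subset_trials / filters.
store_take <- function(store, idx) {
  out <- store
  out$amplitudes <- store$amplitudes[, , idx, drop = FALSE]
  out$meta <- store$meta[idx, , drop = FALSE]
  out
}

#' Apply the standard behavioral/EEG analysis filters
#'
#' Two staged filters mirror how visual-search trials enter the analyses:
#' center-top/center-bottom deviant positions (not assignable to a visual
#' hemifield) and miss trials are excluded from everything; RT and ERP
#' analyses additionally require a correct response and a clean epoch.
#'
#' @param store A [trial_store()].
#' @param stage `"accuracy"` (drop top/bottom deviants and misses) or
#'   `"rt_erp"` (additionally drop error trials and EEG-invalid trials).
#' @param position_col,response_col Metadata column names.
#' @return Filtered [trial_store()]. The filters are a pure conjunction, so
#'   their order of application is irrelevant.
#' @export
apply_analysis_filters <- function(store, stage = c("accuracy", "rt_erp"),
                                   position_col = "deviant_position",
                                   response_col = "response") {
  stage <- match.arg(stage)
  m <- store$meta
  for (col in c(position_col, response_col))
    if (!col %in% names(m))
      abort(sprintf("metadata lacks required column `%s`.", col))
  keep <- !(as.character(m[[position_col]]) %in% c("top", "bottom")) &
    as.character(m[[response_col]]) != "miss"
  if (stage == "rt_erp")
    keep <- keep & as.character(m[[response_col]]) != "error" & m$eeg_valid
  store_take(store, which(keep))
}

#' Per-trial mean amplitude over an ROI and time window
#'
#' @param store A [trial_store()].
#' @param channels Character vector of ROI channel labels.
#' @param window_ms Half-open time window `c(start, end)` in ms.
#' @return Numeric vector, one value per trial (uV): the mean over ROI
#'   channels and window samples. Trials flagged `eeg_valid = FALSE` get
#'   `NaN`.
#' @export
mean_amplitude <- function(store, channels, window_ms) {
  stopifnot(inherits(store, "trial_store"))
  if (length(channels) == 0L) abort("`channels` must name at least one channel.")
  missing <- setdiff(channels, store$channel_labels)
  if (length(missing) > 0)
    abort(sprintf("unknown channel(s): %s", paste(missing, collapse = ", ")))
  sidx <- window_index(store$time_ms, window_ms)
  block <- store$amplitudes[match(channels, store$channel_labels), sidx, ,
                            drop = FALSE]
  vals <- apply(block, 3, mean)
  vals[!store$meta$eeg_valid] <- NaN
  vals
}

#' Append an ROI amplitude column to the store metadata
#'
#' @inheritParams mean_amplitude
#' @param name Name of the new metadata column.
#' @return The store with `meta[[name]]` added.
#' @export
add_roi_amplitude <- function(store, name, channels, window_ms) {
  store$meta[[name]] <- mean_amplitude(store, channels, window_ms)
  store
}

#' Export per-trial ROI amplitudes as a long table
#'
#' Produces the single-trial table consumed by the mixed-model stage: one
#' row per EEG-valid trial, all metadata columns plus the mean ROI
#' amplitude in uV.
#'
#' @inheritParams mean_amplitude
#' @param amplitude_col Name for the amplitude column (default `"amplitude"`).
#' @param path Optional CSV output path.
#' @return A tibble (invisibly also written to `path` if given).
#' @export
export_long <- function(store, channels, window_ms,
                        amplitude_col = "amplitude", path = NULL) {
  vals <- mean_amplitude(store, channels, window_ms)
  out <- store$meta
  out[[amplitude_col]] <- vals
  out <- out[store$meta$eeg_valid, , drop = FALSE]
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
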