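#' Participant-by-condition ERP averages
#'
#' Averages single trials within each participant x condition cell —
#' the aggregation step that feeds the cluster-based permutation test.
#' Cells with zero trials are flagged in the count table (their average is
#' `NA`), never silently zeroed; the permutation-test caller decides how to
#' handle affected participants.
#'
#' @param store A [trial_store()], typically already passed through
#'   [apply_analysis_filters()] so only valid, correct trials remain.
#' @param factors Character vector of metadata factor columns defining the
#'   condition cells (crossed).
#' @return Object of class `condition_averages`: list with `data`
#'   (4-D array participants x cells x channels x samples), `participants`,
#'   `cells` (labels of the factor crossing), `counts` (tibble
#'   participant x cell x n), `time_ms`, `channel_labels`.
#' @export
condition_averages <- function(store, factors) {
  stopifnot(inherits(store, "trial_store"))
  missing <- setdiff(factors, names(store$meta))
  if (length(missing) > 0)
    abort(sprintf("unknown factor column(s): %s", paste(missing, collapse = ", ")))
  cell <- interaction(store$meta[factors], sep = ":", drop = FALSE, lex.order = TRUE)
  participants <- unique(store$meta$participant_id)
  cells <- levels(cell)
  d <- dim(store$amplitudes)
  out <- array(NA_real_,
               dim = c(length(participants), length(cells), d[1], d[2]),
               dimnames = list(participants, cells, store$channel_labels, NULL))
  counts <- tidyr::expand_grid(participant_id = participants, cell = cells)
  counts$n <- 0L
  for (p in seq_along(participants)) {
    for (cc in seq_along(cells)) {
      idx <- which(store$meta$participant_id == participants[p] & cell == cells[cc])
      counts$n[counts$participant_id == participants[p] &
                 counts$cell == cells[cc]] <- length(idx)
      if (length(idx) > 0)
        out[p, cc, , ] <- apply(store$amplitudes[, , idx, drop = FALSE],
                                c(1, 2), mean)
    }
  }
  structure(list(data = out, participants = participants, cells = cells,
                 factors = factors, counts = as_tibble(counts),
                 time_ms = store$time_ms,
                 channel_labels = store$channel_labels),
            class = "condition_averages")
}

#' @export
print.condition_averages <- function(x, ...) {
  cat(sprintf("<condition_averages> %d participants x %d cells (%s) x %d channels x %d samples\n",
              length(x$participants), length(x$cells),
              paste(x$factors, collapse = " x "),
              length(x$channel_labels), length(x$time_ms)))
  empty <- sum(x$counts$n == 0)
  if (empty > 0) cat(sprintf("  %d empty cell(s) flagged (NA averages).\n", empty))
  invisible(x)
}

#' Extract one condition's participant x channel x sample array
#'
#' @param ca A [condition_averages()] object.
#' @param cell Cell label (one of `ca$cells`).
#' @return 3-D array participants x channels x samples, as consumed by
#'   [cbpt_test()].
#' @export
cond_avg <- function(ca, cell) {
  stopifnot(inherits(ca, "condition_averages"))
  ci <- match(cell, ca$cells)
  if (is.na(ci)) abort(sprintf("unknown cell `%s`; available: %s", cell,
                               paste(ca$cells, collapse = ", ")))
  out <- ca$data[, ci, , , drop = FALSE]
  dim(out) <- dim(ca$data)[c(1, 3, 4)]
  dimnames(out) <- list(ca$participants, ca$channel_labels, NULL)
  out
}

#' Regression-based ERP estimation
#'
#' Fits an ordinary least-squares regression of single-trial amplitude on a
#' design built from the metadata, independently at every (channel, sample)
#' point, returning one coefficient waveform per design column. Averaging is
#' the special case of a one-hot condition design without intercept: the
#' betas are then exactly the condition mean waveforms.
#'
#' The system is solved once via the thin QR of the design; a rank-deficient
#' design is rejected with the offending columns named rather than silently
#' aliased.
#'
#' @param store A [trial_store()]; only `eeg_valid` trials enter the fit.
#' @param design A one-sided formula over metadata columns (e.g.
#'   `~ 0 + condition` for per-condition means, `~ rt_ms` for an RT slope).
#' @return Object of class `regression_erp`: list with `beta` (array
#'   coefficients x channels x samples), `coef_names`, `time_ms`,
#'   `channel_labels`, `n_trials`.
#' @export
regression_erp <- function(store, design) {
  stopifnot(inherits(store, "trial_store"))
  keep <- which(store$meta$eeg_valid)
  if (length(keep) == 0L) abort("no EEG-valid trials to fit.")
  X <- model.matrix(design, data = store$meta[keep, , drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("design is rank deficient; collinear column(s): %s",
                  paste(aliased, collapse = ", ")))
  }
  d <- dim(store$amplitudes)
  Y <- matrix(store$amplitudes[, , keep, drop = FALSE],
              nrow = d[1] * d[2], ncol = length(keep))  # (ch*sample) x trial
  B <- t(qr.coef(qrX, t(Y)))                            # (ch*sample) x coef
  beta <- array(t(B), dim = c(ncol(X), d[1], d[2]),
                dimnames = list(colnames(X), store$channel_labels, NULL))
  structure(list(beta = beta, coef_names = colnames(X),
                 time_ms = store$time_ms,
                 channel_labels = store$channel_labels,
                 n_trials = length(keep), design = design),
            class = "regression_erp")
}

#' @export
print.regression_erp <- function(x, ...) {
  cat(sprintf("<regression_erp> %d coefficient waveform(s) over %d channels x %d samples (n = %d trials)\n",
              length(x$coef_names), length(x$channel_labels),
              length(x$time_ms), x$n_trials))
  cat(sprintf("  terms: %s\n", paste(x$coef_names, collapse = ", ")))
  invisible(x)
}

#' Tidy a regression ERP into a long tibble
#'
#' @param x A [regression_erp()] result.
#' @param ... Unused.
#' @return Tibble with columns `term`, `channel`, `time_ms`, `estimate`.
#' @method tidy regression_erp
#' @export
tidy.regression_erp <- function(x, ...) {
  tidyr::expand_grid(term = x$coef_names, channel = x$channel_labels,
                     time_ms = x$time_ms) |>
    dplyr::mutate(estimate = as.vector(aperm(x$beta, c(3, 2, 1))[
      cbind(match(.data$time_ms, x$time_ms),
            match(.data$channel, x$channel_labels),
            match(.data$term, x$coef_names))]))
}

#' Single-trial ERP image sorted by a behavioral key
#'
#' Rows are single trials of one channel, ordered ascending by the sort
#' column (ties broken by recording order, i.e. a stable sort); no smoothing
#' is applied, so what is displayed is exactly what the statistics see.
#'
#' @param store A [trial_store()].
#' @param channel Channel label.
#' @param sort_col Numeric metadata column to sort by (default `"rt_ms"`).
#' @return Object of class `erp_image`: list with `data` (sorted trials x
#'   samples matrix), `sort_values` (sorted key), `order` (original trial
#'   indices in sorted order), `time_ms`, `channel`, `sort_col`.
#' @export
erp_image <- function(store, channel, sort_col = "rt_ms") {
  stopifnot(inherits(store, "trial_store"))
  if (!channel %in% store$channel_labels)
    abort(sprintf("unknown channel `%s`.", channel))
  if (!sort_col %in% names(store$meta))
    abort(sprintf("unknown sort column `%s`.", sort_col))
  key <- store$meta[[sort_col]]
  if (!is.numeric(key)) abort("`sort_col` must be numeric.")
  if (all(is.na(key))) abort(sprintf("sort column `%s` is all NA.", sort_col))
  ord <- order(key, na.last = TRUE)  # stable: ties keep recording order
  mat <- t(store$amplitudes[match(channel, store$channel_labels), , ord])
  structure(list(data = mat, sort_values = key[ord], order = ord,
                 time_ms = store$time_ms, channel = channel,
                 sort_col = sort_col),
            class = "erp_image")
}

#' @export
print.erp_image <- function(x, ...) {
  cat(sprintf("<erp_image> channel %s: %d trials x %d samples, sorted by %s\n",
              x$channel, nrow(x$data), ncol(x$data), x$sort_col))
  invisible(x)
}
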