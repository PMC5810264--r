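# HDF5 persistence for the 3-D trial store.
#
# Schema (version 1.0):
#   /schema_version      string scalar
#   /amplitudes          float64, channels x samples x trials (uV)
#   /time_ms             float64 vector
#   /sampling_rate       float64 scalar
#   /channel_labels      string vector
#   /meta/<column>       one dataset per metadata column; factors stored as
#                        string values plus /meta_levels/<column> with the
#'                       declared level order; logicals stored as int 0/1
#   /meta_columns        column order
#   /meta_class          per-column storage class tag

STORE_SCHEMA_VERSION <- "1.0"

#' Save a trial store to an HDF5 file
#'
#' @param store A [trial_store()].
#' @param path Output `.h5` path (overwritten if present).
#' @return `path`, invisibly.
#' @seealso [load_store()]
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "trial_store"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5w <- function(obj, name) suppressMessages(rhdf5::h5write(obj, path, name))
  h5w(STORE_SCHEMA_VERSION, "schema_version")
  h5w(store$amplitudes, "amplitudes")
  h5w(store$time_ms, "time_ms")
  h5w(store$sampling_rate, "sampling_rate")
  h5w(store$channel_labels, "channel_labels")
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5createGroup(path, "meta_levels")
  cls <- character(0)
  for (col in names(store$meta)) {
    v <- store$meta[[col]]
    if (is.factor(v)) {
      cls[col] <- "factor"
      h5w(as.character(v), paste0("meta/", col))
      h5w(levels(v), paste0("meta_levels/", col))
    } else if (is.logical(v)) {
      cls[col] <- "logical"
      h5w(as.integer(v), paste0("meta/", col))
    } else if (is.numeric(v)) {
      cls[col] <- if (is.integer(v)) "integer" else "double"
      h5w(v, paste0("meta/", col))
    } else {
      cls[col] <- "character"
      h5w(as.character(v), paste0("meta/", col))
    }
  }
  h5w(names(store$meta), "meta_columns")
  h5w(unname(cls), "meta_class")
  invisible(path)
}

#' Load a trial store from an HDF5 file
#'
#' Lossless inverse of [save_store()]: amplitudes, time axis, channel
#' labels, validity flags and all metadata columns (including factor level
#' order) round-trip exactly. A file with a different schema version is
#' rejected rather than guessed at.
#'
#' @param path `.h5` file written by [save_store()].
#' @return A [trial_store()].
#' @export
load_store <- function(path) {
  if (!file.exists(path)) abort(sprintf("store file not found: %s", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5r <- function(name) rhdf5::h5read(path, name)
  ver <- as.character(h5r("schema_version"))
  if (!identical(ver, STORE_SCHEMA_VERSION))
    abort(sprintf("trial-store schema version mismatch: file has %s, this build reads %s.",
                  ver, STORE_SCHEMA_VERSION))
  amplitudes <- h5r("amplitudes")
  if (length(dim(amplitudes)) != 3L)
    amplitudes <- array(amplitudes, dim = c(dim(amplitudes), 1L)[1:3])
  cols <- as.character(h5r("meta_columns"))
  cls <- as.character(h5r("meta_class"))
  meta <- purrr::map2(cols, cls, function(col, cl) {
    v <- h5r(paste0("meta/", col))
    switch(cl,
           factor = factor(as.character(v),
                           levels = as.character(h5r(paste0("meta_levels/", col)))),
           logical = as.logical(v),
           integer = as.integer(v),
           double = as.double(v),
           as.character(v))
  })
  names(meta) <- cols
  trial_store(amplitudes,
              time_ms = as.numeric(h5r("time_ms")),
              channel_labels = as.character(h5r("channel_labels")),
              meta = as_tibble(meta),
              sampling_rate = as.numeric(h5r("sampling_rate")))
}
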