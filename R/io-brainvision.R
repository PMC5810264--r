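# BrainVision (.vhdr/.vmrk/.eeg) reader and writer.
#
# Scope: binary, multiplexed INT_16 and IEEE_FLOAT_32 — the dominant dialect
# written by BrainVision Recorder. Vectorized orientation and ASCII data are
# rejected with an explicit error rather than silently misread.

read_ini_sections <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- out[[section]] %||% character()
    } else if (grepl("=", ln, fixed = TRUE) && !is.na(section)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      out[[section]][key] <- val
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header, the `.vmrk` marker file and the binary `.eeg`
#' payload into a [raw_recording()]. Amplitudes are scaled to microvolts via
#' the per-channel resolution declared in the header.
#'
#' Only the multiplexed binary dialect with `INT_16` or `IEEE_FLOAT_32`
#' samples is supported; anything else raises an explicit error.
#'
#' @param header_path Path to the `.vhdr` header file.
#' @return A [raw_recording()].
#' @seealso [write_brainvision()]
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path))
    abort(sprintf("header file not found: %s", header_path))
  hdr <- read_ini_sections(readLines(header_path, warn = FALSE, encoding = "UTF-8"))
  common <- hdr[["Common Infos"]]
  if (is.null(common))
    abort("not a BrainVision header: missing [Common Infos] section.")

  orientation <- toupper(common["DataOrientation"] %||% "MULTIPLEXED")
  if (!is.na(orientation) && orientation != "MULTIPLEXED")
    abort(sprintf("unsupported BrainVision dialect: DataOrientation=%s (only MULTIPLEXED is supported).",
                  orientation))
  fmt <- toupper(common["DataFormat"] %||% "BINARY")
  if (fmt != "BINARY")
    abort(sprintf("unsupported BrainVision dialect: DataFormat=%s (only BINARY is supported).", fmt))
  binfmt <- toupper(hdr[["Binary Infos"]]["BinaryFormat"] %||% "INT_16")
  if (!binfmt %in% c("INT_16", "IEEE_FLOAT_32"))
    abort(sprintf("unsupported BinaryFormat=%s (supported: INT_16, IEEE_FLOAT_32).", binfmt))

  n_chan <- as.integer(common["NumberOfChannels"])
  if (is.na(n_chan) || n_chan < 1)
    abort("header lacks a valid NumberOfChannels entry.")
  samp_int_us <- as.numeric(common["SamplingInterval"])
  if (is.na(samp_int_us) || samp_int_us <= 0)
    abort("header lacks a valid SamplingInterval entry.")
  sampling_rate <- 1e6 / samp_int_us

  chinfo <- hdr[["Channel Infos"]]
  labels <- character(n_chan); resolution <- rep(1, n_chan)
  for (i in seq_len(n_chan)) {
    entry <- chinfo[sprintf("Ch%d", i)]
    if (is.na(entry)) abort(sprintf("header lacks Channel Infos entry Ch%d.", i))
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    res <- suppressWarnings(as.numeric(parts[3]))
    if (!is.na(res) && res > 0) resolution[i] <- res
  }

  dir <- dirname(header_path)
  data_path <- file.path(dir, common["DataFile"])
  marker_path <- if (!is.na(common["MarkerFile"])) file.path(dir, common["MarkerFile"]) else NA
  if (!file.exists(data_path))
    abort(sprintf("data file referenced by header is missing: %s", data_path))

  n_bytes <- file.size(data_path)
  bytes_per <- if (binfmt == "INT_16") 2L else 4L
  n_samples <- as.integer(n_bytes / (bytes_per * n_chan))
  con <- file(data_path, "rb"); on.exit(close(con))
  raw_vals <- if (binfmt == "INT_16") {
    readBin(con, "integer", n = n_chan * n_samples, size = 2L, signed = TRUE,
            endian = "little")
  } else {
    readBin(con, "numeric", n = n_chan * n_samples, size = 4L, endian = "little")
  }
  data <- matrix(as.numeric(raw_vals), nrow = n_chan)  # multiplexed: channel fastest
  data <- data * resolution

  events <- tibble(sample_index = integer(), code = character())
  if (!is.na(marker_path)) {
    if (!file.exists(marker_path))
      abort(sprintf("marker file referenced by header is missing: %s", marker_path))
    mrk <- read_ini_sections(readLines(marker_path, warn = FALSE, encoding = "UTF-8"))
    minfo <- mrk[["Marker Infos"]]
    if (!is.null(minfo) && length(minfo) > 0) {
      parsed <- lapply(unname(minfo), function(e) strsplit(e, ",", fixed = TRUE)[[1]])
      keep <- vapply(parsed, function(p) length(p) >= 3, logical(1))
      parsed <- parsed[keep]
      if (length(parsed) > 0) {
        events <- tibble(
          sample_index = vapply(parsed, function(p) as.integer(p[3]), integer(1)),
          code = vapply(parsed, function(p) if (nzchar(p[2])) p[2] else p[1],
                        character(1)))
      }
    }
  }

  raw_recording(data, sampling_rate, channel_labels = labels,
                reference_label = unname(common["ReferenceChannel"] %||% NULL) |>
                  (\(x) if (length(x) == 0 || is.na(x)) NULL else x)(),
                events = events,
                meta = list(source = header_path, binary_format = binfmt))
}

#' Write a recording in BrainVision format
#'
#' Produces `<base_path>.vhdr`, `<base_path>.vmrk` and `<base_path>.eeg`
#' readable by [read_brainvision()] (and by standard EEG toolboxes).
#'
#' @param rec A [raw_recording()].
#' @param base_path Output path without extension.
#' @param binary_format `"INT_16"` (default; per-channel resolution chosen so
#'   the full amplitude range fits 16 bits) or `"IEEE_FLOAT_32"` (lossless to
#'   single precision, resolution 1).
#' @return Named character vector of the three paths written, invisibly.
#' @export
write_brainvision <- function(rec, base_path, binary_format = c("INT_16", "IEEE_FLOAT_32")) {
  stopifnot(inherits(rec, "raw_recording"))
  binary_format <- match.arg(binary_format)
  if (ncol(rec$data) == 0L)
    abort("refusing to write a zero-length recording.")
  base <- basename(base_path)
  paths <- c(vhdr = paste0(base_path, ".vhdr"),
             vmrk = paste0(base_path, ".vmrk"),
             eeg  = paste0(base_path, ".eeg"))

  n_chan <- nrow(rec$data)
  if (binary_format == "INT_16") {
    peak <- apply(abs(rec$data), 1, max)
    resolution <- ifelse(peak > 0, peak / 32000, 0.1)
  } else {
    resolution <- rep(1, n_chan)
  }

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", n_chan),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$sampling_rate),
    if (!is.null(rec$reference_label))
      sprintf("ReferenceChannel=%s", rec$reference_label),
    "[Binary Infos]",
    sprintf("BinaryFormat=%s", binary_format),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%.10g,µV", seq_len(n_chan), rec$channel_labels,
            resolution))
  writeLines(hdr, paths["vhdr"], useBytes = FALSE)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    "[Marker Infos]")
  if (nrow(rec$events) > 0) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$events)), rec$events$code,
                        rec$events$sample_index))
  }
  writeLines(mk, paths["vmrk"])

  con <- file(paths["eeg"], "wb")
  on.exit(close(con))
  scaled <- rec$data / resolution  # recycles resolution down columns (channels)
  if (binary_format == "INT_16") {
    writeBin(as.integer(round(as.vector(scaled))), con, size = 2L, endian = "little")
  } else {
    writeBin(as.vector(scaled), con, size = 4L, endian = "little")
  }
  invisible(paths)
}
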