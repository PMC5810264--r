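#' Sensor montage (channel layout)
#'
#' A channel layout is a tibble with one row per channel: `label`, 3-D head
#' coordinates `x`, `y`, `z` (consistent units, e.g. meters on an idealized
#' sphere), and `type` (`"scalp"` or a non-scalp type such as `"eog"`).
#'
#' @param path CSV file with columns `label,x,y,z` and optionally `type`
#'   (defaults to `"scalp"`).
#' @return A tibble of class `channel_layout`.
#' @examples
#' layout <- read_montage(default_montage_path())
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) abort(sprintf("montage file not found: %s", path))
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df)))
    abort("montage CSV must have columns label,x,y,z.")
  if (!"type" %in% names(df)) df$type <- "scalp"
  if (anyDuplicated(df$label))
    abort(sprintf("duplicate channel labels in montage: %s",
                  paste(unique(df$label[duplicated(df$label)]), collapse = ", ")))
  for (cc in c("x", "y", "z")) {
    if (!is.numeric(df[[cc]]))
      abort(sprintf("montage column `%s` must be numeric.", cc))
  }
  scalp <- df$type == "scalp"
  if (any(scalp & !complete.cases(df[, c("x", "y", "z")])))
    abort("every scalp channel must have finite coordinates.")
  structure(df[, c("label", "x", "y", "z", "type")],
            class = c("channel_layout", class(df)))
}

#' Path to the packaged idealized 65-channel montage
#'
#' Idealized spherical 10-10 positions for a 64-channel cap plus the left
#' ear reference A1 (all `scalp`) and an infra-orbital EOG channel IO1
#' (`eog`). These are synthetic standard-position coordinates, not digitized
#' from any participant.
#'
#' @return Path to the montage CSV shipped with the package.
#' @export
default_montage_path <- function() {
  system.file("extdata", "easycap65_synthetic_montage.csv",
              package = "trialerp", mustWork = TRUE)
}
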