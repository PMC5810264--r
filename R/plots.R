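# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_tile
#'   scale_fill_gradient2 labs theme_minimal facet_wrap geom_vline
NULL

#' @export
ggplot2::autoplot

#' Plot an ERP image
#'
#' Heat map of single trials (rows, sorted by the behavioral key) by time,
#' with the sorted key overlaid as a line. No smoothing: the display shows
#' exactly the data the statistics use.
#'
#' @param object An [erp_image()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot erp_image
#' @export
autoplot.erp_image <- function(object, ...) {
  df <- tidyr::expand_grid(trial = seq_len(nrow(object$data)),
                           time_ms = object$time_ms)
  df$amplitude <- as.vector(t(object$data))
  key <- tibble(trial = seq_len(nrow(object$data)),
                time_ms = object$sort_values)
  ggplot(df, aes(x = .data$time_ms, y = .data$trial,
                 fill = .data$amplitude)) +
    geom_raster() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                         name = "uV") +
    geom_line(data = key, aes(x = .data$time_ms, y = .data$trial),
              inherit.aes = FALSE, linewidth = 0.4) +
    labs(x = "time (ms)",
         y = sprintf("trials (sorted by %s)", object$sort_col),
         title = sprintf("ERP image at %s", object$channel)) +
    theme_minimal()
}

#' Plot the significance mask of a cluster permutation test
#'
#' Channel-by-time tiles of the t map with significant cluster membership
#' outlined by opacity.
#'
#' @param object A [cbpt_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cbpt_result
#' @export
autoplot.cbpt_result <- function(object, ...) {
  tmap <- attr(object, "t_map")
  mask <- attr(object, "mask")
  df <- tidyr::expand_grid(channel = rownames(tmap),
                           time_ms = attr(object, "time_ms"))
  df$t <- as.vector(t(tmap))
  df$significant <- as.vector(t(mask))
  df$channel <- factor(df$channel, levels = rev(rownames(tmap)))
  ggplot(df, aes(x = .data$time_ms, y = .data$channel, fill = .data$t,
                 alpha = ifelse(.data$significant, 1, 0.35))) +
    geom_tile() +
    ggplot2::scale_alpha_identity() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    labs(x = "time (ms)", y = NULL,
         title = "cluster permutation test: t map (significant clusters opaque)") +
    theme_minimal()
}

#' Plot condition-average ERPs
#'
#' Grand-average waveform per condition cell at chosen channels.
#'
#' @param object A [condition_averages()] result.
#' @param channels Channels to display (default: first channel).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot condition_averages
#' @export
autoplot.condition_averages <- function(object,
                                        channels = object$channel_labels[1],
                                        ...) {
  chi <- match(channels, object$channel_labels)
  if (anyNA(chi)) abort("unknown channel(s) requested.")
  df <- purrr::map(seq_along(object$cells), function(cc) {
    purrr::map(chi, function(ci) {
      ga <- colMeans(object$data[, cc, ci, , drop = FALSE][, 1, 1, ],
                     na.rm = TRUE)
      tibble(cell = object$cells[cc],
             channel = object$channel_labels[ci],
             time_ms = object$time_ms, amplitude = ga)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  ggplot(df, aes(x = .data$time_ms, y = .data$amplitude,
                 color = .data$cell)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dotted") +
    facet_wrap(~channel) +
    labs(x = "time (ms)", y = "amplitude (uV)", color = NULL) +
    theme_minimal()
}
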