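#' Raster plot of population calcium activity
#'
#' One row per cell, time on the x axis, dF/F (or raw fluorescence) as
#' color — the standard population view in which each line shows a single
#' cell's activity over the recording. Stimulus epochs are overlaid as
#' vertical bands.
#'
#' @param x A `ca_traces` (plots dF/F) or `ca_recording` (plots raw
#'   fluorescence).
#' @param max_cells Downsample to at most this many cells for plotting.
#' @return A ggplot object.
#' @export
plot_raster <- function(x, max_cells = 200) {
  long <- if (inherits(x, "ca_traces")) {
    tidy.ca_traces(x) |> dplyr::rename(value = "dff")
  } else {
    tidy.ca_recording(x) |> dplyr::rename(value = "fluorescence")
  }
  ids <- unique(long$cell_id)
  if (length(ids) > max_cells) {
    keep <- ids[seq(1, length(ids), length.out = max_cells)]
    long <- dplyr::filter(long, .data$cell_id %in% keep)
  }
  protocol <- if (inherits(x, "ca_traces")) x$protocol else x$protocol
  stim <- protocol[protocol$label %in% c(SECRETAGOGUES, "high_K"), ]
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, factor(.data$cell_id))) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::annotate("rect",
      xmin = stim$start_s, xmax = stim$end_s,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red"
    ) +
    ggplot2::scale_fill_viridis_c(name = if (inherits(x, "ca_traces")) "dF/F" else "F (a.u.)") +
    ggplot2::scale_y_discrete(breaks = NULL) +
    ggplot2::labs(x = "time (s)", y = "cell") +
    ggplot2::theme_minimal()
}

#' PCA scatter of tumor fingerprints
#'
#' @param object A `ca_pca` from [run_pca()].
#' @param colour Optional vector (length = tumors) to color points by, e.g.
#'   recurrence status.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 with explained-variance axis labels.
#' @method autoplot ca_pca
#' @export
autoplot.ca_pca <- function(object, colour = NULL, ...) {
  df <- tibble::tibble(
    label = rownames(object$scores) %||% as.character(seq_len(nrow(object$scores))),
    PC1 = object$scores[, 1],
    PC2 = if (ncol(object$scores) > 1) object$scores[, 2] else 0
  )
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(
      if (is.null(colour)) NULL else ggplot2::aes(colour = .data$colour),
      size = 3
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
      vjust = -0.8, size = 3
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$explained_pct[1]),
      y = sprintf(
        "PC2 (%.1f%%)",
        if (length(object$explained_pct) > 1) object$explained_pct[2] else 0
      ),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  p
}

#' Bar chart of a tumor's responsiveness fingerprint
#'
#' @param profile One-row tumor profile from [tumor_summary()].
#' @return A ggplot of the category and per-stimulus percentages.
#' @export
plot_tumor_profile <- function(profile) {
  cols <- grep("^pct_", names(profile), value = TRUE)
  long <- profile |>
    dplyr::select("tumor_id", dplyr::all_of(cols)) |>
    tidyr::pivot_longer(-"tumor_id", names_to = "feature", values_to = "pct") |>
    dplyr::mutate(feature = sub("^pct_", "", .data$feature))
  ggplot2::ggplot(long, ggplot2::aes(.data$feature, .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~tumor_id) +
    ggplot2::labs(x = NULL, y = "% of viable cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
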