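# Lightweight ggplot2 views of merged track sets and version histories.
# These stand in for the graphical client: deletions are drawn as outlines
# only (transparent fill), matching how a tombstoned feature is rendered.

#' Plot a merged track set
#'
#' One horizontal lane per source track; features are drawn as intervals,
#' colored by provenance state. DELETED features keep only their border.
#'
#' @param object A `wb_trackset` from [merge_tracks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wb_trackset <- function(object, ...) {
  d <- as_tibble(object)
  d <- filter(d, .data$start > 0)  # non-positional features have no extent
  d <- d |>
    group_by(.data$source) |>
    mutate(lane = row_number()) |>
    ungroup()
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   ymin = .data$lane - 0.4, ymax = .data$lane + 0.4,
                   fill = .data$state, colour = .data$state,
                   alpha = .data$state == "DELETED")
    ) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 0, `FALSE` = 0.8),
                                guide = "none") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$source), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "amino-acid position", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot the version history of a feature
#'
#' Shows each version's coordinate interval over the edit timeline, labelled
#' by action and author.
#'
#' @param history Version-record tibble from `store$feature_history()` or
#'   [wb_history()].
#' @return A ggplot object.
#' @export
plot_feature_history <- function(history) {
  d <- mutate(history,
              start = map_int(.data$payload, ~ .x$start),
              end = map_int(.data$payload, ~ .x$end))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$version_number)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$version_number,
                                       colour = .data$action),
                          linewidth = 3) +
    ggplot2::geom_text(ggplot2::aes(x = .data$end, label = .data$user_id),
                       hjust = -0.2, size = 3) +
    ggplot2::scale_y_reverse(breaks = d$version_number) +
    ggplot2::labs(x = "amino-acid position", y = "version") +
    ggplot2::theme_minimal()
}
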