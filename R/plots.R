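#' Lineage timeline plot of a tracking result
#'
#' Each track is a horizontal segment over its \[birth, death\] interval;
#' division edges connect a mother's end to its daughters' starts, fusion
#' edges connect parents' ends to the child's start. Tracks are colored by
#' confidence index.
#'
#' @param object A `"tracking_result"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tracking_result <- function(object, ...) {
  tr <- object$tracks
  tr$lane <- order_lanes(object)
  seg <- tr
  edges <- list()
  if (nrow(object$divisions) > 0) {
    for (i in seq_len(nrow(object$divisions))) {
      d <- object$divisions[i, ]
      lane_m <- tr$lane[tr$label == d$mother]
      for (dd in c(d$daughter1, d$daughter2)) {
        edges[[length(edges) + 1]] <- tibble(
          x = d$frame, xend = d$frame + 1L,
          y = lane_m, yend = tr$lane[tr$label == dd],
          kind = "division"
        )
      }
    }
  }
  if (nrow(object$fusions) > 0) {
    for (i in seq_len(nrow(object$fusions))) {
      fu <- object$fusions[i, ]
      lane_c <- tr$lane[tr$label == fu$child]
      for (p in fu$parents[[1]]) {
        edges[[length(edges) + 1]] <- tibble(
          x = fu$frame - 1L, xend = fu$frame,
          y = tr$lane[tr$label == p], yend = lane_c,
          kind = "fusion"
        )
      }
    }
  }
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$birth, xend = .data$death,
                   y = .data$lane, yend = .data$lane,
                   colour = .data$confidence),
      linewidth = 1.5
    ) +
    ggplot2::scale_colour_gradient(limits = c(0, 1), low = "firebrick",
                                   high = "forestgreen") +
    ggplot2::labs(x = "frame", y = "track",
                  colour = "confidence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (length(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = dplyr::bind_rows(edges),
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y, yend = .data$yend,
                   linetype = .data$kind),
      colour = "grey30"
    )
  }
  p
}

# lanes: daughters adjacent to their mother, otherwise birth order
order_lanes <- function(object) {
  tr <- object$tracks
  lane <- rank(tr$birth * (nrow(tr) + 1) + tr$label,
               ties.method = "first")
  as.numeric(lane)
}

#' Trajectory plot of a track set
#'
#' @param object A track tibble (`track`, `frame`, `row`, `col`), e.g. from
#'   [mask_track_set()] or a simulator.
#' @param ... Unused.
#' @return A ggplot object (y axis flipped to match image row order).
#' @export
plot_tracks <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$col, y = .data$row,
                               group = .data$track,
                               colour = factor(.data$track))) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}
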