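#' Flatten annotation geometries for plotting
#'
#' One row per vertex, with ring/polygon grouping columns, ready for
#' `ggplot2::geom_polygon()`/`geom_path()`.
#'
#' @param ann annotation tibble.
#' @return Tibble with columns `id`, `class_name`, `x`, `y`, `ring`,
#'   `hole`, `group`.
#' @export
fortify_annotations <- function(ann) {
  stopifnot(is_annotations(ann))
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    geom <- ann$geometry[[i]]
    rk <- 0L
    for (poly in geom) {
      for (j in seq_along(poly)) {
        rk <- rk + 1L
        r <- poly[[j]]
        rows <- c(rows, list(tibble::tibble(
          id = ann$id[i] %|NA|% sprintf("ann_%03d", i),
          class_name = ann$class_name[i],
          x = r[, 1L], y = r[, 2L],
          ring = rk, hole = j > 1L,
          group = sprintf("%d.%d", i, rk)
        )))
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(id = character(), class_name = character(),
                          x = numeric(), y = numeric(), ring = integer(),
                          hole = logical(), group = character()))
  }
  dplyr::bind_rows(rows)
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' Plot annotations in slide coordinates
#'
#' Outlines colored by class, y axis pointing down to match the image
#' convention.
#'
#' @param ann annotation tibble.
#' @return A ggplot object.
#' @export
plot_annotations <- function(ann) {
  df <- fortify_annotations(ann)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$group,
                                   colour = .data$class_name)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [px]", y = "y [px]", colour = "class")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a label mask
#'
#' Raster view of the label grid (background blank), y down.
#'
#' @param object a [tile_mask()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tile_mask <- function(object, ...) {
  g <- object$grid
  df <- tibble::tibble(
    col = rep(seq_len(ncol(g)) - 1L, each = nrow(g)),
    row = rep(seq_len(nrow(g)) - 1L, times = ncol(g)),
    label = as.vector(g)
  )
  df <- df[df$label > 0L, , drop = FALSE]
  df$class <- class_of(object$label_map, df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col + 0.5, y = .data$row + 0.5,
                                   fill = .data$class)) +
    ggplot2::geom_tile(width = 1, height = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col [px]", y = "row [px]", fill = "class")
}

#' Plot per-shape discretization quality by strategy
#'
#' Boxplots of IoU and Hausdorff distance, one panel per metric.
#'
#' @param object an `annotiler_eval` from [evaluate_dataset()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.annotiler_eval <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("iou", "hd"), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strategy, y = .data$value,
                                   fill = .data$strategy)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "pixel-selection strategy", y = NULL)
}
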