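# ggplot2 graphics: trajectories, ternary-projected simplex fields,
# lattice snapshots.

# project 3-simplex barycentric coordinates to the plane
ternary_xy <- function(a, b, c) {
  # a: bottom-left vertex, b: bottom-right, c: top
  list(px = b + c / 2, py = c * sqrt(3) / 2)
}

#' Plot a strategy-frequency trajectory
#'
#' @param object a `qs_trajectory` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.qs_trajectory <- function(object, ...) {
  long <- tidy(object)
  idcol <- names(long)[1]
  ggplot2::ggplot(long, ggplot2::aes(.data[[idcol]], .data$frequency,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = idcol, y = "frequency", colour = "strategy") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
plot.qs_trajectory <- function(x, ...) print(autoplot.qs_trajectory(x, ...))

#' Plot a simplex vector field
#'
#' Projects the 3-strategy simplex onto the plane (first strategy bottom
#' left, second bottom right, third top) and draws the velocity field as
#' arrows.
#'
#' @param object a `qs_field` tibble (3 strategies).
#' @param arrow_scale multiplier applied to the velocity before drawing.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.qs_field <- function(object, arrow_scale = NULL, ...) {
  xcols <- grep("^x_", names(object), value = TRUE)
  vcols <- grep("^v_", names(object), value = TRUE)
  if (length(xcols) != 3L) {
    stop("simplex plotting needs a 3-strategy field", call. = FALSE)
  }
  pos <- ternary_xy(object[[xcols[1]]], object[[xcols[2]]],
                    object[[xcols[3]]])
  vel <- ternary_xy(object[[vcols[1]]], object[[vcols[2]]],
                    object[[vcols[3]]])
  if (is.null(arrow_scale)) {
    vmax <- max(sqrt(vel$px^2 + vel$py^2))
    arrow_scale <- if (vmax > 0) 0.04 / vmax else 1
  }
  df <- tibble::tibble(px = pos$px, py = pos$py,
                       qx = pos$px + vel$px * arrow_scale,
                       qy = pos$py + vel$py * arrow_scale)
  lab <- sub("^x_", "", xcols)
  corners <- tibble::tibble(
    x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2), label = lab
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$px, y = .data$py,
                   xend = .data$qx, yend = .data$qy),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm")),
      linewidth = 0.3, colour = "grey30"
    ) +
    ggplot2::geom_polygon(data = corners, ggplot2::aes(.data$x, .data$y),
                          fill = NA, colour = "black") +
    ggplot2::geom_text(data = corners,
                       ggplot2::aes(.data$x, .data$y, label = .data$label),
                       vjust = c(1.7, 1.7, -0.9)) +
    ggplot2::coord_equal(clip = "off") +
    ggplot2::theme_void()
}

#' @export
plot.qs_field <- function(x, ...) print(autoplot.qs_field(x, ...))

#' Plot a lattice snapshot
#'
#' @param object a genotype matrix (class `qs_lattice`).
#' @param ... unused.
#' @return A ggplot raster of the strategy occupying each site.
#' @export
autoplot.qs_lattice <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$strategy <- factor(strategy_label(as.character(unclass(object))),
                        levels = .qs_short)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$strategy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_brewer(palette = "Set1", drop = FALSE) +
    ggplot2::theme_void()
}

#' @export
plot.qs_lattice <- function(x, ...) print(autoplot.qs_lattice(x, ...))

#' Plot a steady-state sweep as a genotype-distribution panel grid
#'
#' Stacked genotype frequencies per cell, faceted over up to two sweep axes.
#'
#' @param sweep the tibble returned by [steady_state_sweep()].
#' @param x_axis name of the sweep axis mapped to the x position (default the
#'   first axis column).
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep, x_axis = NULL) {
  meta <- c("genotype", "strategy", "mean_freq", "sd_freq", "failed")
  axes <- setdiff(names(sweep), meta)
  if (is.null(x_axis)) x_axis <- axes[1]
  facet_axes <- setdiff(axes, x_axis)
  sweep$strategy <- factor(sweep$strategy, levels = .qs_short)
  g <- ggplot2::ggplot(sweep,
                       ggplot2::aes(factor(.data[[x_axis]]),
                                    .data$mean_freq,
                                    fill = .data$strategy)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "Set1", drop = FALSE) +
    ggplot2::labs(x = x_axis, y = "steady-state frequency") +
    ggplot2::theme_minimal()
  if (length(facet_axes) == 1L) {
    g <- g + ggplot2::facet_wrap(facet_axes)
  } else if (length(facet_axes) >= 2L) {
    g <- g + ggplot2::facet_grid(
      stats::reformulate(facet_axes[2], facet_axes[1]))
  }
  g
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
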