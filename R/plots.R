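#' Plot the islet fold-change trace
#'
#' General-baseline fold change over the whole recording with the stimulus
#' additions marked and, if available, detected second-phase waves shaded.
#'
#' @param analysis An `islet_analysis`.
#' @return A ggplot object.
#' @export
plot_islet_trace <- function(analysis) {
  stopifnot(inherits(analysis, "islet_analysis"))
  tl <- analysis$timeline
  dt <- tl$frame_interval_s
  df <- tibble(time_s = (seq_along(analysis$islet$fold_change) - 1) * dt,
               fold_change = analysis$islet$fold_change)
  stim <- tibble(
    time_s = c(tl$frame_g11, tl$frame_g25, tl$frame_kcl) * dt,
    label = c("11 mM", "25 mM", "KCl")
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$fold_change)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = stim, ggplot2::aes(xintercept = .data$time_s),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_text(data = stim,
                       ggplot2::aes(x = .data$time_s, y = Inf, label = .data$label),
                       vjust = 1.5, hjust = -0.1, size = 3, colour = "grey30") +
    ggplot2::labs(x = "Time (s)", y = "Fold change (F - Fmin)/Fmin") +
    ggplot2::theme_minimal()
  if (nrow(analysis$waves)) {
    w <- analysis$waves
    p <- p + ggplot2::annotate(
      "rect",
      xmin = (w$activation_frame_abs - 1) * dt,
      xmax = (w$deactivation_frame_abs - 1) * dt,
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "orange"
    )
  }
  p
}

#' Raster plot of binarized cell activity
#'
#' Cells x time binary activity display over the connectivity section:
#' each row is a cell, shaded where its adaptive-baseline fold change is
#' above the binarization threshold.
#'
#' @param analysis An `islet_analysis`.
#' @return A ggplot object.
#' @export
plot_rasterplot <- function(analysis) {
  stopifnot(inherits(analysis, "islet_analysis"))
  dt <- analysis$timeline$frame_interval_s
  thr <- analysis$config$binarize_threshold
  m <- analysis$sf_matrix > thr
  df <- tibble(
    cell = factor(rep(rownames(m), times = ncol(m)), levels = rev(rownames(m))),
    time_s = rep((seq_len(ncol(m)) - 1) * dt, each = nrow(m)),
    active = as.vector(m)
  )
  ggplot2::ggplot(df[df$active, ],
                  ggplot2::aes(x = .data$time_s, y = .data$cell)) +
    ggplot2::geom_tile(fill = "grey15", height = 0.8) +
    ggplot2::labs(x = "Time in section (s)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Heatmap of the coactivity matrix
#'
#' @param result A `coactivity_result` (or an `islet_analysis`).
#' @return A ggplot object.
#' @export
plot_coactivity <- function(result) {
  if (inherits(result, "islet_analysis")) result <- result$coactivity
  stopifnot(inherits(result, "coactivity_result"))
  ids <- result$cell_ids
  df <- tibble(
    a = factor(rep(ids, times = length(ids)), levels = ids),
    b = factor(rep(ids, each = length(ids)), levels = rev(ids)),
    coactivity = as.vector(result$C)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$coactivity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "C_ij") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Topographic network map
#'
#' Nodes at cell centroids, significant edges drawn between them coloured
#' by coactivity; subpopulation labels highlighted when given an
#' `islet_analysis`.
#'
#' @param analysis An `islet_analysis` (with centroids), or a
#'   `coactivity_result` plus a `centroids` tibble.
#' @param centroids Centroid tibble when `analysis` is a
#'   `coactivity_result`.
#' @param significant_only Draw only significant edges (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_network <- function(analysis, centroids = NULL, significant_only = TRUE) {
  if (inherits(analysis, "islet_analysis")) {
    result <- analysis$coactivity
    if (is.null(result)) abort("analysis carries no coactivity result")
    centroids <- analysis$cells[, c("cell_id", "x_px", "y_px")]
    labels <- analysis$cells
  } else {
    result <- analysis
    labels <- NULL
  }
  stopifnot(inherits(result, "coactivity_result"))
  net <- export_network(result, centroids, significant_only = significant_only)
  e <- net$edges
  n <- net$nodes
  e$x <- n$x_px[match(e$source, n$cell_id)]
  e$y <- n$y_px[match(e$source, n$cell_id)]
  e$xend <- n$x_px[match(e$target, n$cell_id)]
  e$yend <- n$y_px[match(e$target, n$cell_id)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$weight),
      alpha = 0.4, linewidth = 0.3
    ) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1), name = "C_ij") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    n <- dplyr::left_join(
      n, labels[, c("cell_id", "is_hub_criterion", "is_hub_top10", "is_leader",
                    "is_first_responder")],
      by = "cell_id"
    )
    n$label <- dplyr::case_when(
      n$is_hub_criterion | n$is_hub_top10 ~ "hub",
      n$is_leader ~ "leader",
      n$is_first_responder ~ "first-responder",
      TRUE ~ "other"
    )
    p <- p + ggplot2::geom_point(
      data = n,
      ggplot2::aes(x = .data$x_px, y = .data$y_px, shape = .data$label,
                   size = .data$label == "other")
    ) +
      ggplot2::scale_size_manual(values = c(`TRUE` = 1, `FALSE` = 2.5),
                                 guide = "none")
  } else {
    p <- p + ggplot2::geom_point(data = n,
                                 ggplot2::aes(x = .data$x_px, y = .data$y_px),
                                 size = 1)
  }
  p
}

#' Histogram of first-responder activation latencies
#'
#' Distribution of per-cell first-phase activation times (FR-T20) with the
#' labeled first-responders highlighted.
#'
#' @param analysis An `islet_analysis`.
#' @param binwidth_s Bin width in seconds (default 5).
#' @return A ggplot object.
#' @export
plot_latency_histogram <- function(analysis, binwidth_s = 5) {
  stopifnot(inherits(analysis, "islet_analysis"))
  df <- analysis$cells[!is.na(analysis$cells$fr_t20_s), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fr_t20_s,
                                   fill = .data$is_first_responder)) +
    ggplot2::geom_histogram(binwidth = binwidth_s, boundary = 0) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                               name = "first-responder") +
    ggplot2::labs(x = "Activation time FR-T20 (s)", y = "Cells") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on an `islet_analysis` dispatches to the named plot:
#' `"trace"` ([plot_islet_trace()]), `"raster"` ([plot_rasterplot()]),
#' `"coactivity"` ([plot_coactivity()]), `"network"` ([plot_network()]) or
#' `"latency"` ([plot_latency_histogram()]). On a `coactivity_result` it
#' draws the heatmap.
#'
#' @param object The result object.
#' @param type Which view of an `islet_analysis` to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.islet_analysis <- function(object,
                                    type = c("trace", "raster", "coactivity",
                                             "network", "latency"),
                                    ...) {
  switch(match.arg(type),
         trace = plot_islet_trace(object),
         raster = plot_rasterplot(object),
         coactivity = plot_coactivity(object),
         network = plot_network(object),
         latency = plot_latency_histogram(object))
}

#' @rdname autoplot.islet_analysis
#' @export
autoplot.coactivity_result <- function(object, ...) plot_coactivity(object)
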