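# ggplot2 views of the main result types.

#' Plot a replacement-index series with its Zahnreihen
#'
#' Reproduces the standard Zahnreihen graph: tooth position on the x-axis,
#' replacement index on the y-axis, one line per Zahnreihe.
#'
#' @param object A series tibble (e.g. from [segment_zahnreihen()]; a
#'   `zahnreihe_id` column is added if absent).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zr_series <- function(object, ...) {
  if (!"zahnreihe_id" %in% names(object)) {
    object <- segment_zahnreihen(object)
  }
  facets <- intersect(c("specimen_id", "element", "side"), names(object))
  p <- ggplot(object, aes(x = .data$position, y = .data$replacement_index,
                          group = .data$zahnreihe_id)) +
    geom_line(aes(colour = factor(.data$zahnreihe_id))) +
    geom_point(aes(shape = if ("tooth_class" %in% names(object))
      .data$tooth_class else NULL)) +
    labs(x = "Tooth position (rostral → caudal)",
         y = "Replacement index", colour = "Zahnreihe",
         shape = "Tooth class") +
    theme_minimal()
  if (length(facets) > 0) {
    p <- p + facet_wrap(facets)
  }
  p
}

#' Plot an increment-width series
#'
#' @param object An increment table.
#' @param ... Unused.
#' @return A ggplot object: daily couplet width against day index, one
#'   panel per sectioned tooth.
#' @export
autoplot.increment_table <- function(object, ...) {
  ggplot(object, aes(x = .data$day_index, y = .data$width_um)) +
    geom_line(colour = "grey60") +
    geom_point(size = 0.8) +
    facet_wrap(c("specimen_id", "tooth_id"), scales = "free_x") +
    labs(x = "Day (von Ebner couplet index)",
         y = "Increment width (µm)") +
    theme_minimal()
}

#' Plot node-state posterior frequencies
#'
#' Stacked posterior state frequencies per internal node from
#' model-averaged stochastic maps.
#'
#' @param object An `asr_result` from [model_averaged_maps()].
#' @param internal_only Drop tip nodes (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asr_result <- function(object, internal_only = TRUE, ...) {
  post <- object$node_posterior
  n_tip <- length(object$fits[[1]]$tree$tip.label)
  if (internal_only) post <- filter(post, .data$node > n_tip)
  ggplot(post, aes(x = factor(.data$node), y = .data$frequency,
                   fill = .data$state)) +
    geom_col() +
    labs(x = "Node", y = "Posterior frequency", fill = "State") +
    theme_minimal()
}

#' Plot an ontogenetic trend
#'
#' @param object An `ontogeny_trend` from [ontogenetic_trend()].
#' @param ... Unused.
#' @return A ggplot object: one panel per metric, specimens in ontogenetic
#'   order.
#' @export
autoplot.ontogeny_trend <- function(object, ...) {
  long <- purrr::pmap_dfr(
    list(object$metric, object$specimens, object$values),
    function(m, s, v) tibble(metric = m, specimen = factor(s, levels = s),
                             value = v)
  )
  ggplot(long, aes(x = .data$specimen, y = .data$value, group = 1)) +
    geom_line(colour = "grey50") +
    geom_point() +
    facet_wrap("metric", scales = "free_y") +
    labs(x = "Specimen (ontogenetic order)", y = "Count") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
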