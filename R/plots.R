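# ggplot2 views of the main result types, shaped like the figures a survey
# of this kind reports: per-species classification histograms, per-node event
# bubbles on the time axis, recombination summaries and per-chromosome ncRNA
# counts.

#' Per-species element counts by supergroup
#'
#' @param elements Element tibble with `species` and `classification`, or a
#'   `herv_discovery` object.
#' @return A ggplot.
#' @export
plot_classification <- function(elements) {
  if (inherits(elements, "herv_discovery")) elements <- elements$elements
  ggplot2::ggplot(elements,
                  ggplot2::aes(x = .data$species, fill = .data$classification)) +
    ggplot2::geom_bar() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "full-length elements", fill = "supergroup") +
    ggplot2::theme_minimal()
}

#' Transmission events per dated tree node
#'
#' Bubble view of event counts against node age (a minimum integration time).
#'
#' @param x A `herv_transmission` object.
#' @return A ggplot.
#' @export
plot_event_nodes <- function(x) {
  stopifnot(inherits(x, "herv_transmission"))
  d <- summarize_events(x)$per_node %>% filter(.data$n_events > 0L)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_mya, y = .data$label,
                                  size = .data$n_events,
                                  colour = .data$classification)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "node age (MYA)", y = NULL, size = "events",
                  colour = "supergroup") +
    ggplot2::theme_minimal()
}

#' Recombination-involved elements by species and supergroup
#'
#' @param x A `herv_recombination` object (or its `summary` tibble).
#' @return A ggplot.
#' @export
plot_recombination_summary <- function(x) {
  d <- if (inherits(x, "herv_recombination")) x$summary else x
  ggplot2::ggplot(d, ggplot2::aes(x = .data$species, y = .data$n_elements,
                                  fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "recombination-involved elements",
                  fill = "supergroup") +
    ggplot2::theme_minimal()
}

#' ncRNA-associated elements per chromosome
#'
#' @param tbl Annotation tibble (see [read_herv_ncrna_table()]).
#' @return A ggplot.
#' @export
plot_ncrna_chromosomes <- function(tbl) {
  d <- tbl %>% count(.data$chromosome, .data$classification)
  d$chromosome <- factor(d$chromosome,
                         levels = c(as.character(1:22), "X", "Y"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chromosome, y = .data$n,
                                  fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "chromosome", y = "ncRNA-associated elements",
                  fill = "supergroup") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.herv_discovery <- function(object, ...) plot_classification(object)

#' @export
autoplot.herv_transmission <- function(object, ...) plot_event_nodes(object)

#' @export
autoplot.herv_recombination <- function(object, ...) {
  plot_recombination_summary(object)
}
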