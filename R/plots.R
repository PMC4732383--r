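#' Plot per-area lineage accumulation
#'
#' Step curves of lineage counts per area through time (time axis
#' reversed: past on the left).
#'
#' @param ltt A [lineage_accumulation()] tibble.
#' @return A ggplot object.
#' @export
plot_area_ltt <- function(ltt) {
  ggplot2::ggplot(ltt, ggplot2::aes(x = .data$age, y = .data$lineages,
                                    colour = .data$area)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (Ma)", y = "Lineages",
                  colour = "Area") +
    ggplot2::theme_minimal()
}

#' Plot a model-comparison table
#'
#' AICc per model, best model first.
#'
#' @param comparison A [compare_models()] tibble (a `stratified` column,
#'   if present, is used for facetting).
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(comparison) {
  p <- ggplot2::ggplot(
    comparison,
    ggplot2::aes(x = .data$AICc,
                 y = stats::reorder(.data$model, -.data$AICc))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "AICc", y = NULL) +
    ggplot2::theme_minimal()
  if ("stratified" %in% names(comparison)) {
    p <- p + ggplot2::facet_wrap(
      ggplot2::vars(ifelse(comparison$stratified, "time-stratified",
                           "non-stratified")))
  }
  p
}

#' @export
autoplot.dec_comparison <- function(object, ...) {
  plot_model_comparison(object)
}

#' Plot ancestral-range marginals for selected nodes
#'
#' Stacked probability bars per internal node — the tabular equivalent of
#' node pie charts.
#'
#' @param marginals An [ancestral_marginals()] tibble.
#' @param nodes Optional node numbers to restrict to.
#' @param min_prob States below this probability are pooled as "other".
#' @return A ggplot object.
#' @export
plot_ancestral_marginals <- function(marginals, nodes = NULL,
                                     min_prob = 0.05) {
  if (!is.null(nodes)) {
    marginals <- dplyr::filter(marginals, .data$node %in% nodes)
  }
  marginals <- dplyr::mutate(
    marginals,
    state = ifelse(.data$prob < min_prob, "other", .data$state))
  ggplot2::ggplot(marginals,
                  ggplot2::aes(x = factor(.data$node), y = .data$prob,
                               fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Node", y = "Marginal probability",
                  fill = "Range") +
    ggplot2::theme_minimal()
}
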