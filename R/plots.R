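#' Plot a cross-validation report
#'
#' Per-fold accuracies with their mean; if the report comes from
#' [greedy_select()], the accepted selection path (mean accuracy after each
#' added feature) is shown instead, mirroring the score-vs-features bar
#' panels of the two classification scenarios.
#'
#' @param object A `parenclitic_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parenclitic_cv <- function(object, ...) {
  if (!is.null(object$step_scores)) {
    df <- tibble::tibble(
      step = factor(seq_along(object$step_scores)),
      label = vapply(seq_along(object$selected_features), function(i) {
        paste(object$selected_features[seq_len(i)], collapse = " + ")
      }, character(1)),
      score = object$step_scores)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$score)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$score)),
                         vjust = -0.4, size = 3) +
      ggplot2::scale_x_discrete(labels = df$label) +
      ggplot2::coord_cartesian(ylim = c(0.5, min(1, max(df$score) + 0.05))) +
      ggplot2::labs(x = NULL, y = "mean CV accuracy",
                    title = paste0("Greedy selection path (",
                                   object$scenario, " scenario)")) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
  } else {
    df <- tidy(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$accuracy)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = object$mean_score, linetype = 2) +
      ggplot2::scale_x_continuous(breaks = df$fold) +
      ggplot2::labs(y = "fold accuracy",
                    title = paste0("Cross-validation (", object$scenario,
                                   " scenario)")) +
      ggplot2::theme_minimal()
  }
}

#' Plot the raw-vs-enhanced scenario comparison
#'
#' Side-by-side greedy selection paths of the two scenarios.
#'
#' @param object A `parenclitic_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parenclitic_comparison <- function(object, ...) {
  paths <- dplyr::bind_rows(lapply(c("raw", "enhanced"), function(scen) {
    rep <- object[[scen]]
    tibble::tibble(
      scenario = scen, step = seq_along(rep$step_scores),
      label = vapply(seq_along(rep$selected_features), function(i) {
        paste(rep$selected_features[seq_len(i)], collapse = " + ")
      }, character(1)),
      score = rep$step_scores)
  }))
  paths$scenario <- factor(paths$scenario, levels = c("raw", "enhanced"))
  ggplot2::ggplot(paths, ggplot2::aes(x = factor(.data$step), y = .data$score,
                                      fill = .data$scenario)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$score)),
                       vjust = -0.4, size = 3) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::coord_cartesian(ylim = c(0.5, min(1, max(paths$score) + 0.05))) +
    ggplot2::labs(x = "features added (greedy order)",
                  y = "mean CV accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a parenclitic network
#'
#' The binarized network drawn with a force-directed layout; node size
#' reflects degree, edge alpha the absolute Z-score weight.
#'
#' @param object A binarized `parenclitic_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parenclitic_network <- function(object, ...) {
  if (is.null(object$binary)) abort("binarize() the network first")
  g <- as_igraph(object)
  # layout ignores the signed Z-score weights
  lay <- igraph::layout_with_fr(g, weights = NA)
  nodes <- tibble::tibble(x = lay[, 1], y = lay[, 2],
                          name = igraph::V(g)$name,
                          degree = igraph::degree(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble::tibble(
    x = lay[el[, 1], 1], y = lay[el[, 1], 2],
    xend = lay[el[, 2], 1], yend = lay[el[, 2], 2],
    w = abs(igraph::E(g)$weight))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       alpha = .data$w),
                          linewidth = 0.3, show.legend = FALSE) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$degree),
                        colour = "firebrick", show.legend = FALSE) +
    ggplot2::labs(title = paste0("Parenclitic network, subject ",
                                 object$subject_id)) +
    ggplot2::theme_void()
}

#' Class-wise distributions of the network features
#'
#' Density plots of link density and information content for survivors vs
#' non-survivors, the visual check of whether the network representation
#' separates the classes.
#'
#' @param features A [featurize()] table.
#' @param cohort The cohort table the networks came from (for the labels).
#' @param label_col Label column name.
#' @return A ggplot object.
#' @export
plot_feature_densities <- function(features, cohort, label_col = "DEATH") {
  lab <- check_label(cohort, label_col)
  df <- dplyr::inner_join(
    features,
    tibble::tibble(subject_id = as.character(cohort$subject_id),
                   status = factor(ifelse(lab == 1, "died", "survived"))),
    by = "subject_id")
  long <- tidyr::pivot_longer(df, c("link_density", "information_content"),
                              names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$status)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}
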