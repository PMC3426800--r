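#' Plot a concept graph
#'
#' Draws the curated neighborhood of the seed: nodes placed by a
#' force-directed (Fruchterman–Reingold) layout, colored by BFS depth, with
#' edge opacity proportional to the cosine weight and surviving relation
#' labels written along the edges.
#'
#' @param object A `concept_graph`.
#' @param label_edges Draw relation labels on labeled edges (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concept_graph
#' @export
autoplot.concept_graph <- function(object, label_edges = TRUE, ...) {
  ig <- as_igraph(object)
  set.seed(1) # layout jitter only; fixed for reproducible figures
  xy <- igraph::layout_with_fr(ig)
  nodes <- tibble(
    cui = object$nodes$cui,
    depth = factor(object$nodes$depth),
    x = xy[, 1], y = xy[, 2]
  )
  p <- ggplot2::ggplot()
  if (nrow(object$edges) > 0) {
    edges <- object$edges |>
      left_join(nodes[c("cui", "x", "y")], by = c(u = "cui")) |>
      left_join(nodes[c("cui", "x", "y")], by = c(v = "cui"), suffix = c("", "end"))
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   alpha = .data$weight),
      color = "grey40"
    )
    labeled <- edges[!is.na(edges$relation), , drop = FALSE]
    if (label_edges && nrow(labeled) > 0) {
      p <- p + ggplot2::geom_text(
        data = labeled,
        ggplot2::aes(x = (.data$x + .data$xend) / 2, y = (.data$y + .data$yend) / 2,
                     label = .data$relation),
        size = 2.6, color = "grey30", vjust = -0.4
      )
    }
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$depth,
                   shape = .data$cui == object$seed),
      size = 3
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$cui),
      size = 2.8, vjust = 1.8
    ) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 17, `FALSE` = 16), guide = "none") +
    ggplot2::scale_alpha_continuous(range = c(0.25, 1), limits = c(0, 1)) +
    ggplot2::labs(color = "BFS depth", alpha = "cosine",
                  title = sprintf("Concept graph around %s", object$seed)) +
    ggplot2::theme_void()
}

#' Plot seed-activation distributions of predictions
#'
#' Histogram of final seed activations; when gold labels are given the
#' distribution is split by true status, which makes the separation behind
#' the decision threshold visible.
#'
#' @param object Prediction tibble from [classify_patients()].
#' @param gold Optional gold labels tibble.
#' @param threshold Optional threshold to mark as a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_activations <- function(object, gold = NULL, threshold = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(gold)) {
    gold <- gold_labels(gold)
    df <- left_join(df, gold, by = "patient_id", suffix = c("", "_gold"))
    df$status <- ifelse(df$label_gold, "case", "control")
  } else {
    df$status <- "patient"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$seed_activation, fill = .data$status)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "seed activation after spreading", y = "patients", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}

#' @method autoplot phenotype_eval
#' @export
autoplot.phenotype_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)), vjust = -0.4) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
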