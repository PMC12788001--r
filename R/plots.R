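# ggplot2 views of the main result types. These are quick-look diagnostics
# (an in-silico gel, a sensitivity ladder, a screen summary), not
# publication figures.

#' @describeIn specificity_matrix Tile plot of the specificity matrix:
#'   primer pairs vs species, labelled with predicted band sizes -- an
#'   in-silico analogue of the specificity gels.
#' @param object A `scar_specificity` tibble.
#' @param ... Unused.
#' @export
autoplot.scar_specificity <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(bands = map_chr(.data$amplicon_bp,
                           ~ if (length(.x)) paste(.x, collapse = ",") else ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$pair_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$positive), colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$bands), size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey95"),
                               name = "amplified") +
    ggplot2::labs(x = "template species", y = "primer pair") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn simulate_dilution_series Detection ladder across the dilution
#'   series (percent of assay on a log scale).
#' @param object A `scar_dilution` tibble.
#' @param ... Unused.
#' @export
autoplot.scar_dilution <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percent_of_assay,
                                   y = factor(.data$replicate))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$detected), size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#31a354", `FALSE` = "grey70"),
                                 name = "detected") +
    ggplot2::labs(x = "template input (% of assay)", y = "replicate") +
    ggplot2::theme_minimal()
}

#' @describeIn screen_mixture Per-product detection map of the screen.
#' @param object A `scar_screen` object.
#' @param ... Unused.
#' @export
autoplot.scar_screen <- function(object, ...) {
  ggplot2::ggplot(object$detail,
                  ggplot2::aes(x = .data$species, y = .data$sample_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$detected), colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#de2d26", `FALSE` = "grey95"),
                               name = "detected") +
    ggplot2::labs(x = "species assay", y = "product") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn bootstrap_support Rectangular cladogram of the bootstrapped
#'   NJ tree with support labels on internal nodes.
#' @param object A `scar_boottree`.
#' @param ... Unused.
#' @export
autoplot.scar_boottree <- function(object, ...) {
  tree <- object$tree
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  ord <- ape::reorder.phylo(tree, "postorder")
  y <- rep(NA_real_, max(tree$edge))
  y[seq_len(n_tip)] <- match(seq_len(n_tip), rev(ord$edge[ord$edge[, 2] <= n_tip, 2]))
  for (e in seq_len(nrow(ord$edge))) {  # postorder: children before parents
    p <- ord$edge[e, 1]
    kids <- ord$edge[ord$edge[, 1] == p, 2]
    y[p] <- mean(y[kids])
  }
  seg <- tibble(
    x = depth[ord$edge[, 1]], xend = depth[ord$edge[, 2]],
    y = y[ord$edge[, 2]], yend = y[ord$edge[, 2]],
    vy = y[ord$edge[, 1]]
  )
  tips <- tibble(x = depth[seq_len(n_tip)], y = y[seq_len(n_tip)],
                 label = tree$tip.label)
  nodes <- tibble(x = depth[(n_tip + 1):max(tree$edge)],
                  y = y[(n_tip + 1):max(tree$edge)],
                  label = tree$node.label %||% "")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = .data$vy, yend = .data$y)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                       hjust = -0.05, size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                       hjust = 1.1, vjust = -0.4, size = 2.7, colour = "grey30") +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.25))) +
    ggplot2::labs(x = "K2P distance", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}
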