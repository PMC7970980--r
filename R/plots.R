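# ggplot2 displays for the three result types: ploidy histograms with
# labeled peaks, haplotype networks, and recombination scan traces.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_vline geom_point
#'   geom_segment geom_line geom_text labs theme_minimal scale_size_area
NULL

#' @export
ggplot2::autoplot

#' Plot a ploidy diagnosis
#'
#' Fluorescence histogram with detected peaks marked and labeled by their
#' relative ploidy.
#'
#' @param object A `dn_diagnosis` from [diagnose_ploidy()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dn_diagnosis
#' @export
autoplot.dn_diagnosis <- function(object, ...) {
  if (is.null(object$histogram)) {
    abort("This diagnosis carries no histogram; use diagnose_ploidy().")
  }
  h <- object$histogram
  p <- object$peaks
  ggplot(h, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = attr(h, "binwidth"), fill = "grey70") +
    geom_vline(
      data = p,
      aes(xintercept = .data$mean, colour = .data$label),
      linewidth = 0.7
    ) +
    labs(
      x = "fluorescence (a.u.)", y = "events",
      colour = "peak",
      title = sprintf("%s (aneuploid fraction %.2f)",
                      object$status, object$aneuploid_fraction)
    ) +
    theme_minimal()
}

#' Plot a haplotype network
#'
#' Observed haplotypes as circles sized by frequency, inferred medians as
#' small points, unit edges as single-mutation steps. The layout is
#' deterministic (Fruchterman-Reingold under a fixed seed).
#'
#' @param object A `haplotype_network`.
#' @param label Draw haplotype ids.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot haplotype_network
#' @export
autoplot.haplotype_network <- function(object, label = TRUE, ...) {
  coords <- withr::with_seed(
    1, igraph::layout_with_fr(object$graph)
  )
  nodes <- mutate(object$nodes, x = coords[, 1], y = coords[, 2])
  edges <- object$unit_edges
  edges <- left_join(edges, select(nodes, "id", "x", "y"),
                     by = c(from = "id"))
  edges <- left_join(edges, select(nodes, "id", xend = "x", yend = "y"),
                     by = c(to = "id"))
  g <- ggplot() +
    geom_segment(
      data = edges,
      aes(x = .data$x, y = .data$y, xend = .data$xend,
          yend = .data$yend),
      colour = "grey50"
    ) +
    geom_point(
      data = filter(nodes, .data$median),
      aes(x = .data$x, y = .data$y), size = 1, colour = "black"
    ) +
    geom_point(
      data = filter(nodes, !.data$median),
      aes(x = .data$x, y = .data$y, size = .data$frequency),
      colour = "steelblue", alpha = 0.8
    ) +
    scale_size_area(max_size = 10) +
    theme_minimal() +
    labs(x = NULL, y = NULL, size = "frequency")
  if (label) {
    g <- g + geom_text(
      data = filter(nodes, !.data$median),
      aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1, size = 3
    )
  }
  g
}

#' Plot a recombination scan trace
#'
#' Per-window mismatch counts against each parent, with the refined
#' breakpoints as vertical lines.
#'
#' @param object A `recombination_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recombination_scan
#' @export
autoplot.recombination_scan <- function(object, ...) {
  tr <- tidyr::pivot_longer(
    select(object$trace, "window_start", "window_end",
           "mism_a", "mism_b"),
    c("mism_a", "mism_b"),
    names_to = "parent", values_to = "mismatches"
  )
  tr$parent <- ifelse(tr$parent == "mism_a", "A", "B")
  ggplot(tr, aes(x = .data$window_start + 0.5 *
                   (.data$window_end - .data$window_start),
                 y = .data$mismatches, colour = .data$parent)) +
    geom_line() +
    geom_vline(xintercept = object$breakpoints, linetype = "dashed") +
    labs(x = "alignment position (bp)", y = "mismatches in window",
         title = object$query) +
    theme_minimal()
}
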