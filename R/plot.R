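#' Plot an analyzed school network
#'
#' Draws the analyzed friendship network with vertices coloured by
#' detected community and mixed (kin) links dashed.  Layout is
#' Fruchterman-Reingold with a fixed RNG seed so repeated plots of the
#' same analysis coincide.
#'
#' @param x a `school_network_analysis`.
#' @param vertex.size,vertex.label passed to `igraph::plot.igraph`.
#' @param seed layout seed.
#' @param ... further arguments for `igraph::plot.igraph`.
#' @return `x`, invisibly.
#' @export
plot.school_network_analysis <- function(x, vertex.size = 5,
                                         vertex.label = NA, seed = 1, ...) {
  g <- as_igraph(x$network)
  memb <- x$partition$assignment[igraph::V(g)$name]
  pal <- grDevices::hcl.colors(max(memb), palette = "Dark 3")
  lty <- if (n_edges(x$network) > 0)
    ifelse(x$network$mixed, 2, 1) else NULL
  layout <- with_seed(seed, igraph::layout_with_fr(g))
  igraph::plot.igraph(g, layout = layout, vertex.color = pal[memb],
                      vertex.size = vertex.size,
                      vertex.label = vertex.label,
                      edge.lty = lty, ...)
  invisible(x)
}
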