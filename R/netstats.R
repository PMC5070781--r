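#' Network summary statistics
#'
#' These functions compute the standard descriptors of a friendship
#' network: average degree \eqn{\langle k\rangle = 2m/n}, density
#' \eqn{\rho = 2m/(n(n-1))}, clustering coefficient, component structure,
#' and the giant component, plus the within-classroom link probability
#' P_in.
#'
#' @name netstats
NULL

#' @describeIn netstats Average degree 2m/n.
#' @export
average_degree <- function(net) {
  stopifnot(inherits(net, "friendship_network"))
  n <- n_nodes(net)
  if (n == 0L) stop("empty network", call. = FALSE)
  2 * n_edges(net) / n
}

#' @describeIn netstats Density 2m/(n(n-1)).
#' @export
net_density <- function(net) {
  stopifnot(inherits(net, "friendship_network"))
  n <- n_nodes(net)
  if (n <= 1L) stop("density needs at least two nodes", call. = FALSE)
  2 * n_edges(net) / (n * (n - 1))
}

#' Clustering coefficient
#'
#' `method = "avg_local"` averages the local clustering coefficient over
#' all nodes, with nodes of degree < 2 contributing 0;
#' `method = "transitivity"` is the global ratio
#' 3 x (number of triangles) / (number of connected triples).
#'
#' @param net a `friendship_network`.
#' @param method `"avg_local"` (default) or `"transitivity"`.
#' @return A number in \[0, 1\] (0 for degenerate graphs).
#' @export
clustering_coefficient <- function(net,
                                   method = c("avg_local", "transitivity")) {
  stopifnot(inherits(net, "friendship_network"))
  method <- match.arg(method)
  if (n_nodes(net) == 0L) stop("empty network", call. = FALSE)
  g <- as_igraph(net)
  if (method == "avg_local") {
    local <- igraph::transitivity(g, type = "local", isolates = "zero")
    mean(local)
  } else {
    val <- igraph::transitivity(g, type = "global")
    if (is.nan(val)) 0 else val
  }
}

#' Component structure
#'
#' Isolated nodes (degree 0) are counted separately from *nontrivial*
#' components (connected components with at least two nodes); that
#' convention is required to report a disconnected network with many
#' singletons coherently.
#'
#' @param net a `friendship_network`.
#' @return A list with `count_nontrivial`, `isolated`, and `members`
#'   (list of node-id vectors, one per nontrivial component, ordered by
#'   decreasing size then edge count then smallest id).
#' @export
network_components <- function(net) {
  stopifnot(inherits(net, "friendship_network"))
  g <- as_igraph(net)
  comp <- igraph::components(g)
  members <- split(net$node_ids, comp$membership)
  sizes <- lengths(members)
  nontrivial <- members[sizes >= 2L]
  if (length(nontrivial)) {
    ecounts <- vapply(nontrivial, function(ids)
      n_edges(induced_network(net, ids)), integer(1))
    first_id <- vapply(nontrivial, min, character(1))
    ord <- order(-lengths(nontrivial), -ecounts, first_id)
    nontrivial <- nontrivial[ord]
  }
  list(count_nontrivial = length(nontrivial),
       isolated = sum(sizes == 1L),
       members = unname(lapply(nontrivial, sort)))
}

#' Giant component
#'
#' The induced subgraph on the largest connected component; ties are
#' broken by edge count, then by smallest lexicographic node id.
#'
#' @param net a `friendship_network` with at least one edge.
#' @return A `friendship_network`.
#' @export
giant_component <- function(net) {
  stopifnot(inherits(net, "friendship_network"))
  if (n_edges(net) == 0L) stop("edgeless network has no giant component",
                               call. = FALSE)
  comps <- network_components(net)
  induced_network(net, comps$members[[1L]])
}

#' Within/between-classroom link probabilities
#'
#' P_in is the fraction of edges whose endpoints share a classroom;
#' P_out = 1 - P_in.
#'
#' @param net a `friendship_network` with m > 0.
#' @param roster a `school_roster` covering every edge endpoint.
#' @return Named numeric vector `c(p_in =, p_out =)`.
#' @export
classroom_link_probabilities <- function(net, roster) {
  stopifnot(inherits(net, "friendship_network"),
            inherits(roster, "school_roster"))
  m <- n_edges(net)
  if (m == 0L) stop("link probabilities undefined for m = 0", call. = FALSE)
  cls <- stats::setNames(roster$table$classroom, roster$table$id)
  c1 <- cls[net$edges[, 1L]]
  c2 <- cls[net$edges[, 2L]]
  if (anyNA(c1) || anyNA(c2))
    stop("edge endpoint missing from roster", call. = FALSE)
  p_in <- sum(c1 == c2) / m
  c(p_in = p_in, p_out = 1 - p_in)
}

#' Full network summary
#'
#' One record with every headline descriptor: n, m, mixed links and
#' their percentage, connectedness, average degree, density, clustering,
#' isolated nodes, nontrivial components, and the giant component's
#' n_g, m_g and average degree.  A network is *connected* only if it has
#' a single nontrivial component and no isolated nodes.
#'
#' @param net a `friendship_network` (mixed flags set if relevant).
#' @param clustering_method passed to [clustering_coefficient()].
#' @return An object of class `"network_summary"` (a named list).
#' @export
summarize_network <- function(net, clustering_method = "avg_local") {
  stopifnot(inherits(net, "friendship_network"))
  n <- n_nodes(net)
  m <- n_edges(net)
  mix <- mixed_count(net)
  comps <- network_components(net)
  if (m > 0L) {
    gc <- giant_component(net)
    n_g <- n_nodes(gc); m_g <- n_edges(gc)
    k_g <- average_degree(gc)
  } else {
    n_g <- 0L; m_g <- 0L; k_g <- NA_real_
  }
  out <- list(
    n = n,
    m = m,
    mixed_count = mix,
    mixed_pct = if (m > 0L) 100 * mix / m else 0,
    connected = comps$count_nontrivial == 1L && comps$isolated == 0L,
    avg_degree = if (n > 0L) 2 * m / n else NA_real_,
    density = if (n > 1L) 2 * m / (n * (n - 1)) else NA_real_,
    clustering = clustering_coefficient(net, clustering_method),
    isolated = comps$isolated,
    components = comps$count_nontrivial,
    n_g = n_g,
    m_g = m_g,
    avg_degree_giant = k_g
  )
  structure(out, class = "network_summary")
}

#' @export
print.network_summary <- function(x, digits = 3, ...) {
  cat("Network summary\n")
  cat(sprintf("  nodes (n)                  %d\n", x$n))
  cat(sprintf("  links (m)                  %d\n", x$m))
  cat(sprintf("  mixed links                %d (%s%%)\n", x$mixed_count,
              format(round_half_up(x$mixed_pct, 2))))
  cat(sprintf("  connected                  %s\n",
              if (x$connected) "yes" else "no"))
  cat(sprintf("  average degree <k>         %.2f\n", x$avg_degree))
  cat(sprintf("  density rho                %.3f\n", x$density))
  cat(sprintf("  clustering C               %.3f\n", x$clustering))
  cat(sprintf("  isolated nodes             %d\n", x$isolated))
  cat(sprintf("  components (size >= 2)     %d\n", x$components))
  cat(sprintf("  giant component n_g, m_g   %d, %d  (<k_g> = %.2f)\n",
              x$n_g, x$m_g, x$avg_degree_giant))
  invisible(x)
}

#' @export
as.data.frame.network_summary <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}
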