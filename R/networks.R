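#' Directed nomination networks and undirected friendship networks
#'
#' A *nomination network* holds the raw directed survey data: an arc
#' (i, j) means student i named student j as a friend.  A *friendship
#' network* is the undirected simple graph obtained after reciprocity
#' filtering; each edge optionally carries a `mixed` flag marking
#' friendship ties that are also sibling/relative ties.
#'
#' Node ids are opaque strings.  Edges are stored as a two-column
#' character matrix with each row sorted so that `edge[1] < edge[2]`,
#' and rows sorted lexicographically, which makes all downstream output
#' deterministic.
#'
#' @param node_ids character vector of unique node identifiers.
#' @param arcs two-column character matrix (or data frame) of ordered
#'   (nominator, nominee) pairs.
#' @param edges two-column character matrix (or data frame) of unordered
#'   node pairs.
#' @param mixed logical vector, one flag per edge (recycled from `FALSE`).
#' @return An object of class `"nomination_network"` or
#'   `"friendship_network"`.
#' @examples
#' net <- friendship_network(c("a", "b", "c"), rbind(c("a", "b")))
#' net
#' @name school_networks
NULL

as_pair_matrix <- function(x, what = "pair") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(x) || length(x) == 0L) {
    return(matrix(character(0), ncol = 2L))
  }
  if (is.vector(x) && length(x) == 2L) x <- matrix(x, ncol = 2L)
  if (!is.matrix(x) || ncol(x) != 2L)
    stop(sprintf("%s set must be a two-column matrix", what), call. = FALSE)
  storage.mode(x) <- "character"
  dimnames(x) <- NULL
  x
}

#' @rdname school_networks
#' @export
nomination_network <- function(node_ids, arcs) {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("duplicate node ids", call. = FALSE)
  arcs <- as_pair_matrix(arcs, "arc")
  if (nrow(arcs)) {
    if (any(arcs[, 1L] == arcs[, 2L]))
      stop("self-nominations are not allowed", call. = FALSE)
    bad <- setdiff(c(arcs), node_ids)
    if (length(bad))
      stop("arc endpoint(s) not in node set: ", paste(bad, collapse = ", "),
           call. = FALSE)
    arcs <- unique(arcs)
    arcs <- arcs[order(arcs[, 1L], arcs[, 2L]), , drop = FALSE]
  }
  structure(list(node_ids = node_ids, arcs = arcs),
            class = "nomination_network")
}

#' @rdname school_networks
#' @export
friendship_network <- function(node_ids, edges, mixed = NULL) {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("duplicate node ids", call. = FALSE)
  edges <- as_pair_matrix(edges, "edge")
  if (nrow(edges)) {
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed", call. = FALSE)
    bad <- setdiff(c(edges), node_ids)
    if (length(bad))
      stop("edge endpoint(s) not in node set: ", paste(bad, collapse = ", "),
           call. = FALSE)
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L), drop = FALSE]
    if (is.null(mixed)) mixed <- rep(FALSE, nrow(edges))
    if (length(mixed) != nrow(edges))
      stop("mixed flag length must equal edge count", call. = FALSE)
    key <- paste(edges[, 1L], edges[, 2L])
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    mixed <- as.logical(mixed)[keep]
    ord <- order(edges[, 1L], edges[, 2L])
    edges <- edges[ord, , drop = FALSE]
    mixed <- mixed[ord]
  } else {
    mixed <- logical(0)
  }
  structure(list(node_ids = node_ids, edges = edges, mixed = mixed),
            class = "friendship_network")
}

#' @export
print.nomination_network <- function(x, ...) {
  cat(sprintf("Nomination network: %d nodes, %d directed arcs\n",
              length(x$node_ids), nrow(x$arcs)))
  invisible(x)
}

#' @export
print.friendship_network <- function(x, ...) {
  cat(sprintf("Friendship network: %d nodes, %d edges (%d mixed)\n",
              length(x$node_ids), nrow(x$edges), sum(x$mixed)))
  invisible(x)
}

#' Number of nodes / edges
#'
#' @param net a `friendship_network` or `nomination_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$node_ids)

#' @rdname n_nodes
#' @export
n_edges <- function(net) {
  if (inherits(net, "nomination_network")) nrow(net$arcs) else nrow(net$edges)
}

#' Node degrees of a friendship network
#'
#' @param net a `friendship_network`.
#' @return Named integer vector over all nodes (isolated nodes get 0).
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "friendship_network"))
  d <- integer(length(net$node_ids))
  names(d) <- net$node_ids
  if (nrow(net$edges)) {
    tab <- table(c(net$edges))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Dense adjacency matrix in node-id order
#'
#' @param net a `friendship_network`.
#' @return Symmetric 0/1 matrix with dimnames = node ids.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "friendship_network"))
  n <- length(net$node_ids)
  A <- matrix(0, n, n, dimnames = list(net$node_ids, net$node_ids))
  if (nrow(net$edges)) {
    i <- match(net$edges[, 1L], net$node_ids)
    j <- match(net$edges[, 2L], net$node_ids)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' Convert to an igraph object
#'
#' Vertex names are node ids; the edge attribute `mixed` is carried over.
#' Used internally wherever a standard graph routine (components,
#' clustering, GraphML) is delegated to igraph.
#'
#' @param net a `friendship_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "friendship_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$node_ids), name = net$node_ids)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, t(net$edges), mixed = net$mixed)
  }
  g
}

#' Induced subgraph on a node subset
#'
#' @param net a `friendship_network`.
#' @param ids node ids to keep.
#' @return A `friendship_network` on `ids` with edges internal to `ids`.
#' @export
induced_network <- function(net, ids) {
  stopifnot(inherits(net, "friendship_network"))
  ids <- as.character(ids)
  bad <- setdiff(ids, net$node_ids)
  if (length(bad)) stop("unknown node id(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  keep <- net$edges[, 1L] %in% ids & net$edges[, 2L] %in% ids
  friendship_network(ids, net$edges[keep, , drop = FALSE], net$mixed[keep])
}

#' School roster: classroom/grade/gender plus kinship ties
#'
#' @param table data frame with columns `id`, `classroom`, and optionally
#'   `grade` and `gender` (`"M"`, `"F"` or `"unknown"`).
#' @param kinship data frame with columns `id1`, `id2`,
#'   `relation` (`"sibling"` or `"relative"`); unordered pairs.
#' @return An object of class `"school_roster"`.
#' @export
school_roster <- function(table, kinship = NULL) {
  stopifnot(is.data.frame(table), all(c("id", "classroom") %in% names(table)))
  table$id <- as.character(table$id)
  table$classroom <- as.character(table$classroom)
  if (anyDuplicated(table$id))
    stop("duplicate id rows in roster", call. = FALSE)
  if (any(is.na(table$classroom) | table$classroom == ""))
    stop("empty classroom in roster row", call. = FALSE)
  if (is.null(table$grade)) table$grade <- NA_integer_
  table$gender <- normalize_gender(if (is.null(table$gender)) "" else table$gender)
  if (is.null(kinship)) {
    kinship <- data.frame(id1 = character(0), id2 = character(0),
                          relation = character(0))
  }
  kinship <- normalize_kinship(kinship)
  structure(list(table = table[c("id", "classroom", "grade", "gender")],
                 kinship = kinship),
            class = "school_roster")
}

normalize_gender <- function(g) {
  g <- toupper(trimws(as.character(g)))
  g[g %in% c("M", "MALE", "B", "BOY")] <- "M"
  g[g %in% c("F", "FEMALE", "G", "GIRL")] <- "F"
  g[!(g %in% c("M", "F"))] <- "unknown"
  g
}

normalize_kinship <- function(kin) {
  stopifnot(is.data.frame(kin),
            all(c("id1", "id2", "relation") %in% names(kin)))
  kin$id1 <- as.character(kin$id1)
  kin$id2 <- as.character(kin$id2)
  kin$relation <- tolower(trimws(as.character(kin$relation)))
  if (any(kin$id1 == kin$id2))
    stop("kinship pair with identical endpoints", call. = FALSE)
  bad <- setdiff(kin$relation, c("sibling", "relative"))
  if (length(bad))
    stop("unknown kinship relation: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  if (nrow(kin)) {
    swap <- kin$id1 > kin$id2
    tmp <- kin$id1[swap]; kin$id1[swap] <- kin$id2[swap]; kin$id2[swap] <- tmp
    # sibling outranks relative when the same pair is stated twice
    kin$relation <- factor(kin$relation, levels = c("sibling", "relative"))
    kin <- kin[order(kin$id1, kin$id2, kin$relation), , drop = FALSE]
    kin <- kin[!duplicated(paste(kin$id1, kin$id2)), , drop = FALSE]
    kin$relation <- as.character(kin$relation)
    rownames(kin) <- NULL
  }
  kin[c("id1", "id2", "relation")]
}

#' @export
print.school_roster <- function(x, ...) {
  cat(sprintf("School roster: %d students, %d classrooms, %d kinship pairs\n",
              nrow(x$table), length(unique(x$table$classroom)),
              nrow(x$kinship)))
  invisible(x)
}

#' Classroom sizes from a roster
#'
#' Sizes count all enrolled students in the roster (not just those present
#' in a network), which is the denominator the confinement rule uses.
#'
#' @param roster a `school_roster`.
#' @return Named integer vector, classroom id -> size.
#' @export
classroom_sizes <- function(roster) {
  stopifnot(inherits(roster, "school_roster"))
  tab <- table(roster$table$classroom)
  stats::setNames(as.integer(tab), names(tab))
}
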