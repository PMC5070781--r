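#' Read a square adjacency matrix from CSV
#'
#' The expected dialect is a square 0/1 matrix whose first row and first
#' column both hold the node ids (in the same order).  In undirected mode
#' the matrix must be symmetric; in directed mode each nonzero cell
#' (i, j) becomes the arc i -> j.
#'
#' @param path path to a CSV file.
#' @param directed logical; read as directed nominations (`TRUE`) or as an
#'   undirected friendship network (`FALSE`).
#' @return A `nomination_network` (directed) or `friendship_network`.
#' @export
read_adjacency <- function(path, directed = FALSE) {
  raw <- utils::read.csv(path, check.names = FALSE, row.names = 1,
                         stringsAsFactors = FALSE)
  M <- as.matrix(raw)
  if (nrow(M) != ncol(M))
    stop("adjacency matrix is not square: ", nrow(M), " x ", ncol(M),
         call. = FALSE)
  ids <- rownames(M)
  if (!identical(ids, colnames(M)))
    stop("row and column ids differ", call. = FALSE)
  if (!all(M %in% c(0, 1)))
    stop("adjacency cells must be 0 or 1", call. = FALSE)
  if (any(diag(M) != 0))
    stop("nonzero diagonal (self-links) in adjacency matrix", call. = FALSE)
  if (directed) {
    idx <- which(M == 1, arr.ind = TRUE)
    nomination_network(ids, cbind(ids[idx[, 1L]], ids[idx[, 2L]]))
  } else {
    if (!isTRUE(all.equal(M, t(M))))
      stop("asymmetric matrix read in undirected mode", call. = FALSE)
    idx <- which(M == 1 & upper.tri(M), arr.ind = TRUE)
    friendship_network(ids, cbind(ids[idx[, 1L]], ids[idx[, 2L]]))
  }
}

#' Read a two-column edge list (TSV)
#'
#' @param path path to a tab-separated file with header `source<TAB>target`.
#' @param directed logical, as in [read_adjacency()].
#' @param nodes optional character vector giving the full node universe
#'   (so isolated nodes survive the round trip); endpoints found in the
#'   file are always included.
#' @return A `nomination_network` or `friendship_network`.
#' @export
read_edgelist <- function(path, directed = FALSE, nodes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("edge list needs two columns", call. = FALSE)
  pairs <- as.matrix(df[, 1:2])
  ids <- sort(unique(c(as.character(nodes), c(pairs))))
  if (directed) nomination_network(ids, pairs)
  else friendship_network(ids, pairs)
}

#' Read a roster CSV (id, classroom, grade, gender)
#'
#' Gender tokens are normalized to `M`/`F`/`unknown`; blanks map to
#' `unknown`.  Duplicate ids and empty classrooms are errors.
#'
#' @param path path to a CSV file with columns `id`, `classroom`, and
#'   optionally `grade` and `gender`.
#' @return A `school_roster` (with an empty kinship set).
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("id", "classroom") %in% names(df)))
    stop("roster needs columns id, classroom", call. = FALSE)
  if (!is.null(df$grade)) {
    df$grade <- suppressWarnings(as.integer(df$grade))
  }
  school_roster(df)
}

#' Read a kinship CSV (id1, id2, relation) into a roster
#'
#' Pairs are stored unordered; if the same pair is stated both as sibling
#' and relative, sibling wins.  A pair with identical endpoints or an
#' unknown relation token is an error.
#'
#' @param path path to a CSV file with columns `id1`, `id2`, `relation`.
#' @param roster a `school_roster` to attach the pairs to.
#' @return The updated `school_roster`.
#' @export
read_kinship <- function(path, roster) {
  stopifnot(inherits(roster, "school_roster"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("id1", "id2", "relation") %in% names(df)))
    stop("kinship file needs columns id1, id2, relation", call. = FALSE)
  roster$kinship <- normalize_kinship(df)
  roster
}

#' Reciprocity filtering: directed nominations to undirected friendships
#'
#' Friendship is treated as a reciprocal concept: the edge \{i, j\} is kept
#' iff both arcs (i, j) and (j, i) were nominated; all non-reciprocal links
#' are suppressed.  The node set is preserved, so students whose every
#' nomination was unreciprocated remain as isolated nodes.
#'
#' @param net a `nomination_network`.
#' @return A `friendship_network` on the same node set.
#' @export
symmetrize_reciprocal <- function(net) {
  stopifnot(inherits(net, "nomination_network"))
  if (!nrow(net$arcs))
    return(friendship_network(net$node_ids, NULL))
  fwd <- paste(net$arcs[, 1L], net$arcs[, 2L], sep = "\r")
  rev <- paste(net$arcs[, 2L], net$arcs[, 1L], sep = "\r")
  keep <- fwd %in% rev & net$arcs[, 1L] < net$arcs[, 2L]
  friendship_network(net$node_ids, net$arcs[keep, , drop = FALSE])
}

#' Flag mixed links (friendship ties that are also kin ties)
#'
#' An edge is *mixed* iff its unordered pair appears in the roster's
#' kinship set.  Kinship pairs with no corresponding friendship edge are
#' ignored — no edge is ever added.  Neither n nor m changes.
#'
#' @param net a `friendship_network`.
#' @param roster a `school_roster` carrying kinship pairs.
#' @return The network with its `mixed` flags set.
#' @export
flag_mixed_links <- function(net, roster) {
  stopifnot(inherits(net, "friendship_network"),
            inherits(roster, "school_roster"))
  kin <- roster$kinship
  if (!nrow(net$edges) || !nrow(kin)) {
    net$mixed <- rep(FALSE, nrow(net$edges))
    return(net)
  }
  a <- pmin(kin$id1, kin$id2); b <- pmax(kin$id1, kin$id2)
  kin_key <- paste(a, b, sep = "\r")
  edge_key <- paste(net$edges[, 1L], net$edges[, 2L], sep = "\r")
  net$mixed <- edge_key %in% kin_key
  net
}

#' Count of mixed links
#'
#' @param net a `friendship_network` whose mixed flags have been set.
#' @return Integer.
#' @export
mixed_count <- function(net) {
  stopifnot(inherits(net, "friendship_network"))
  sum(net$mixed)
}

#' Remove all mixed links
#'
#' Deletes every flagged edge; the node set is unchanged, so the edge
#' count satisfies m_new = m - #mixed exactly and students who kept only
#' kin-friend ties become isolated nodes.
#'
#' @param net a `friendship_network` with mixed flags computed.
#' @return A new `friendship_network` without the mixed edges.
#' @export
remove_mixed_links <- function(net) {
  stopifnot(inherits(net, "friendship_network"))
  keep <- !net$mixed
  friendship_network(net$node_ids, net$edges[keep, , drop = FALSE],
                     net$mixed[keep])
}

#' Write a network (and optional annotations) to disk
#'
#' `format = "graphml"` writes via igraph with node attributes
#' `classroom`, `gender`, `community`, `class_label` (where available)
#' and the edge attribute `mixed`; `format = "edgelist"` writes the
#' two-column TSV dialect [read_edgelist()] reads; `format = "adjacency"`
#' writes the square CSV dialect [read_adjacency()] reads.
#'
#' @param net a `friendship_network`.
#' @param path output file path.
#' @param format one of `"graphml"`, `"edgelist"`, `"adjacency"`.
#' @param roster optional `school_roster` for node attributes.
#' @param partition optional `community_partition` for community indices.
#' @param labels optional named character vector node id -> class label.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist",
                                                "adjacency"),
                          roster = NULL, partition = NULL, labels = NULL) {
  stopifnot(inherits(net, "friendship_network"))
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- data.frame(source = net$edges[, 1L], target = net$edges[, 2L])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "adjacency") {
    A <- adjacency_matrix(net)
    utils::write.csv(A, path, quote = FALSE)
  } else {
    g <- as_igraph(net)
    if (!is.null(roster)) {
      idx <- match(igraph::V(g)$name, roster$table$id)
      igraph::V(g)$classroom <- roster$table$classroom[idx]
      igraph::V(g)$gender <- roster$table$gender[idx]
    }
    if (!is.null(partition)) {
      igraph::V(g)$community <-
        as.integer(partition$assignment[igraph::V(g)$name])
    }
    if (!is.null(labels)) {
      igraph::V(g)$class_label <- unname(labels[igraph::V(g)$name])
    }
    if (n_edges(net) == 0L) {
      # igraph skips the attribute block for edgeless graphs; force the
      # mixed attribute to exist so round trips stay lossless
      g <- igraph::set_edge_attr(g, "mixed", value = logical(0))
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML file written by [write_network()]
#'
#' @param path path to a GraphML file.
#' @return A list with elements `network` (a `friendship_network`, mixed
#'   flags restored) and `attributes` (data frame of node attributes).
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ids <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  mixed <- igraph::edge_attr(g, "mixed")
  if (is.null(mixed)) mixed <- rep(FALSE, nrow(el))
  net <- friendship_network(ids, el, as.logical(mixed))
  attrs <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (a in setdiff(igraph::vertex_attr_names(g), c("name", "id")))
    attrs[[a]] <- igraph::vertex_attr(g, a)
  list(network = net, attributes = attrs)
}
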