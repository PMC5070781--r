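#' Spectral modularity community detection
#'
#' Communities are found by recursive bisection driven by the leading
#' eigenvector of the modularity matrix
#' \deqn{B_{ij} = A_{ij} - \frac{k_i k_j}{2m},}
#' where \eqn{k_i} is the degree of node i and m the total number of
#' edges.  Each group is split by the sign pattern of the leading
#' eigenvector of its generalized modularity matrix
#' \deqn{B^{(g)}_{ij} = B_{ij} - \delta_{ij}\sum_{k\in g} B_{ik},}
#' and a split is kept only when the modularity gain
#' \eqn{\Delta Q = \frac{1}{4m} s^\top B^{(g)} s} is positive.  When the
#' most negative eigenvalue dominates in magnitude, the matrix is first
#' shifted by \eqn{B - \lambda I} (\eqn{\lambda} the dominant negative
#' eigenvalue) so that the leading eigenvector is the dominant one; the
#' shift changes no eigenvector and all reported eigenvalues and
#' modularity values refer to the unshifted matrix.
#'
#' @name spectral
NULL

#' Modularity matrix of a friendship network
#'
#' @param net a `friendship_network` with at least one edge.
#' @return An object of class `"modularity_context"`: a list with
#'   `node_order`, the dense symmetric matrix `B`, total edge count `m`,
#'   and the degree vector `degrees`.
#' @export
modularity_matrix <- function(net) {
  stopifnot(inherits(net, "friendship_network"))
  if (n_edges(net) == 0L)
    stop("modularity matrix undefined for an edgeless network",
         call. = FALSE)
  A <- adjacency_matrix(net)
  k <- rowSums(A)
  m <- sum(A) / 2
  B <- A - outer(k, k) / (2 * m)
  structure(list(node_order = net$node_ids, B = B, m = m, degrees = k),
            class = "modularity_context")
}

#' Leading eigenpair, with the dominant-negative shift
#'
#' Returns the most positive eigenvalue and its eigenvector.  If the most
#' negative eigenvalue exceeds it in absolute value, the shifted matrix
#' B - lambda_min I is formed and decomposed and *its* leading eigenvector
#' is returned (identical up to sign to the unshifted one), flagged
#' `shifted = TRUE`; the reported eigenvalue is always that of the
#' unshifted matrix.
#'
#' @param B dense symmetric matrix.
#' @return List with `value`, `vector`, `shifted`.
#' @export
leading_eigenpair <- function(B) {
  if (!is.matrix(B) || nrow(B) != ncol(B) ||
      !isTRUE(all.equal(B, t(B), tolerance = 1e-8)))
    stop("B must be a symmetric matrix", call. = FALSE)
  if (nrow(B) == 1L)
    return(list(value = B[1L, 1L], vector = 1, shifted = FALSE))
  e <- eigen(B, symmetric = TRUE)
  b_max <- e$values[1L]
  b_min <- e$values[length(e$values)]
  shifted <- abs(b_min) > b_max
  if (shifted) {
    es <- eigen(B - b_min * diag(nrow(B)), symmetric = TRUE)
    vec <- es$vectors[, 1L]
  } else {
    vec <- e$vectors[, 1L]
  }
  list(value = b_max, vector = as.numeric(vec), shifted = shifted)
}

#' Sign vector of an eigenvector
#'
#' Component i is -1 when the eigenvector entry is zero or negative and
#' +1 otherwise; the two signs define the two groups of a bisection.
#'
#' @param v numeric vector.
#' @return Integer vector of +/-1.
#' @export
sign_vector <- function(v) {
  if (!length(v)) stop("empty eigenvector", call. = FALSE)
  ifelse(v <= 0, -1L, 1L)
}

#' Modularity of a bisection (quadratic form)
#'
#' \eqn{Q = \frac{1}{4m} s^\top B s} over the full network.  Identical,
#' within numerical tolerance, to the eigen-expansion
#' \eqn{\frac{1}{4m}\sum_i \beta_i (v_i^\top s)^2}
#' (see [modularity_eigen_expansion()]).
#'
#' @param ctx a `modularity_context`.
#' @param s sign vector of +/-1 over all nodes.
#' @return Numeric Q.
#' @export
modularity_q <- function(ctx, s) {
  stopifnot(inherits(ctx, "modularity_context"))
  if (length(s) != nrow(ctx$B))
    stop("sign vector length must match matrix dimension", call. = FALSE)
  as.numeric(s %*% ctx$B %*% s) / (4 * ctx$m)
}

#' Eigen-expansion form of Q / delta-Q
#'
#' Computes \eqn{\frac{1}{4m}\sum_i \beta_i (v_i^\top s)^2} from the full
#' eigendecomposition of `B`.  Provided to check the quadratic-form
#' implementation against the spectral expansion; the two agree to
#' numerical precision.
#'
#' @param B symmetric matrix (full B or a generalized submatrix).
#' @param s sign vector matching `B`.
#' @param m total edge count of the original network.
#' @return Numeric value.
#' @export
modularity_eigen_expansion <- function(B, s, m) {
  e <- eigen(B, symmetric = TRUE)
  sum(e$values * as.numeric(crossprod(e$vectors, s))^2) / (4 * m)
}

#' Generalized modularity matrix for a subgroup
#'
#' Restricts B to the rows/columns of `group` and corrects the diagonal
#' by the within-group row sums, so that a further split of the group
#' changes total modularity by the quadratic form of this matrix.  Row
#' sums of the result are exactly zero; with `group` equal to all nodes
#' it coincides with B.
#'
#' @param ctx a `modularity_context`.
#' @param group character vector of node ids (at least 2).
#' @return Dense symmetric matrix with dimnames = group ids.
#' @export
generalized_matrix <- function(ctx, group) {
  stopifnot(inherits(ctx, "modularity_context"))
  group <- as.character(group)
  if (length(group) < 2L)
    stop("group must contain at least two nodes", call. = FALSE)
  idx <- match(group, ctx$node_order)
  if (anyNA(idx)) stop("group contains unknown node ids", call. = FALSE)
  Bg <- ctx$B[idx, idx, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bg)
  Bg
}

#' Modularity change of splitting a subgroup
#'
#' \eqn{\Delta Q = \frac{1}{4m} s_g^\top B^{(g)} s_g}, with m from the
#' original network.  Zero for the trivial all-ones split.
#'
#' @param ctx a `modularity_context`.
#' @param group node ids of the subgroup.
#' @param s_g sign vector over the subgroup.
#' @return Numeric delta-Q.
#' @export
delta_q <- function(ctx, group, s_g) {
  Bg <- generalized_matrix(ctx, group)
  if (length(s_g) != nrow(Bg))
    stop("sign vector length must match group size", call. = FALSE)
  as.numeric(s_g %*% Bg %*% s_g) / (4 * ctx$m)
}

#' Direct modularity of a full partition
#'
#' \eqn{Q = \sum_c \left(e_c/m - (d_c/2m)^2\right)}, where e_c is the
#' number of edges inside community c and d_c the total degree of its
#' members.  Used as the authoritative Q of a finished partition and as
#' the consistency check on the accumulated bisection gains.
#'
#' @param net a `friendship_network`.
#' @param membership named vector (node id -> community) or unnamed in
#'   node order.
#' @return Numeric Q.
#' @export
partition_modularity <- function(net, membership) {
  stopifnot(inherits(net, "friendship_network"))
  m <- n_edges(net)
  if (m == 0L) stop("modularity undefined for m = 0", call. = FALSE)
  if (is.null(names(membership))) {
    stopifnot(length(membership) == n_nodes(net))
    names(membership) <- net$node_ids
  }
  deg <- degrees(net)
  comm <- membership[net$node_ids]
  same <- comm[net$edges[, 1L]] == comm[net$edges[, 2L]]
  e_c <- tapply(rep(1L, sum(same)), comm[net$edges[same, 1L]], sum)
  d_c <- tapply(deg, comm, sum)
  e_by <- stats::setNames(rep(0, length(d_c)), names(d_c))
  if (length(e_c)) e_by[names(e_c)] <- e_c
  sum(e_by / m - (d_c / (2 * m))^2)
}

#' Detect communities by recursive leading-eigenvector bisection
#'
#' Runs the full recursive procedure described in [spectral]: the root
#' split is kept when its modularity Q is positive (beyond `tol`), each
#' further split when its delta-Q is positive; a group whose sign vector
#' comes out uniform is indivisible and terminal.  Community indices are
#' contiguous and ordered by each community's smallest node id.
#'
#' The network should normally be connected (the pipeline passes the
#' giant component); disconnected input is accepted with a warning and
#' necessarily ends with components in separate communities.
#'
#' @param net a `friendship_network` with at least one edge.
#' @param tol strict-positivity tolerance for accepting a split.
#' @param trace logical; message one line per bisection attempt.
#' @return An object of class `"community_partition"`: list with
#'   `assignment` (named integer vector node id -> community),
#'   `n_communities`, `Q` (direct-formula modularity), `trace`
#'   (data frame of bisection steps) and `tol`.
#' @export
detect_communities <- function(net, tol = 1e-10, trace = FALSE) {
  stopifnot(inherits(net, "friendship_network"))
  if (n_edges(net) == 0L)
    stop("cannot detect communities in an edgeless network", call. = FALSE)
  comps <- network_components(net)
  if (comps$count_nontrivial + comps$isolated > 1L)
    warning("network is disconnected; components will end in separate ",
            "communities", call. = FALSE)
  ctx <- modularity_matrix(net)
  groups <- list()
  steps <- list()
  recurse <- function(ids) {
    if (length(ids) < 2L) {
      groups[[length(groups) + 1L]] <<- ids
      return(invisible())
    }
    Bg <- generalized_matrix(ctx, ids)
    lead <- leading_eigenpair(Bg)
    s <- sign_vector(lead$vector)
    dq <- as.numeric(s %*% Bg %*% s) / (4 * ctx$m)
    uniform <- length(unique(s)) == 1L
    accepted <- !uniform && dq > tol
    steps[[length(steps) + 1L]] <<- data.frame(
      group_size = length(ids), eigenvalue = lead$value,
      shifted = lead$shifted, delta_q = dq, accepted = accepted)
    if (trace)
      message(sprintf("group of %d: beta=%.5f shifted=%s dQ=%.6f %s",
                      length(ids), lead$value, lead$shifted, dq,
                      if (accepted) "split" else "terminal"))
    if (!accepted) {
      groups[[length(groups) + 1L]] <<- ids
    } else {
      recurse(ids[s > 0])
      recurse(ids[s < 0])
    }
    invisible()
  }
  recurse(ctx$node_order)
  # number communities by smallest contained node id
  groups <- groups[order(vapply(groups, min, character(1)))]
  assignment <- integer(length(ctx$node_order))
  names(assignment) <- ctx$node_order
  for (i in seq_along(groups)) assignment[groups[[i]]] <- i
  trace_df <- do.call(rbind, steps)
  structure(list(assignment = assignment,
                 n_communities = length(groups),
                 Q = partition_modularity(net, assignment),
                 trace = trace_df,
                 tol = tol),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d nodes in %d communities, Q = %.4f\n",
              length(x$assignment), x$n_communities, x$Q))
  invisible(x)
}

#' @export
summary.community_partition <- function(object, ...) {
  sizes <- as.integer(table(object$assignment))
  cat(sprintf("Communities: %d  (Q = %.4f)\n", object$n_communities,
              object$Q))
  cat("Sizes: ", paste(sort(sizes, decreasing = TRUE), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("Bisection attempts: %d (%d accepted, %d with spectral shift)\n",
              nrow(object$trace), sum(object$trace$accepted),
              sum(object$trace$shifted)))
  invisible(object)
}

#' Write a partition to CSV (id, community)
#'
#' @param partition a `community_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "community_partition"))
  df <- data.frame(id = names(partition$assignment),
                   community = as.integer(partition$assignment))
  df <- df[order(df$id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
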