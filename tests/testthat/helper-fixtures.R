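# fixture builders and independent oracles, all generated in code

triangle_net <- function(ids = c("a", "b", "c")) {
  friendship_network(ids, rbind(ids[c(1, 2)], ids[c(2, 3)], ids[c(1, 3)]))
}

two_triangles_net <- function() {
  friendship_network(letters[1:6],
                     rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                           c("d", "e"), c("e", "f"), c("d", "f")))
}

complete_net <- function(n) {
  ids <- sprintf("k%02d", seq_len(n))
  friendship_network(ids, t(utils::combn(ids, 2)))
}

star_net <- function(n_leaves = 4) {
  ids <- c("hub", sprintf("l%d", seq_len(n_leaves)))
  friendship_network(ids, cbind("hub", ids[-1]))
}

# Erdos-Renyi G(n, p) on string ids, deterministic under seed
random_net <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  friendship_network(ids, pairs[keep, , drop = FALSE])
}

# connected random graph (redraws until connected)
random_connected_net <- function(n, p, seed) {
  for (s in seed + 0:50) {
    net <- random_net(n, p, s)
    if (n_edges(net) > 0) {
      comps <- network_components(net)
      if (comps$count_nontrivial == 1 && comps$isolated == 0) return(net)
    }
  }
  stop("could not draw a connected graph")
}

# --- independent modularity oracle ---------------------------------------
# direct formula from the edge list; written independently of the package
# internals (and cross-checked against igraph::modularity in the suite)
oracle_modularity <- function(net, membership) {
  m <- nrow(net$edges)
  mm <- membership[net$node_ids]
  k <- table(factor(c(net$edges), levels = net$node_ids))
  within <- mm[net$edges[, 1]] == mm[net$edges[, 2]]
  d_c <- tapply(as.numeric(k), mm, sum)
  sum(within) / m - sum((d_c / (2 * m))^2)
}

# all set partitions of n elements as membership vectors (restricted
# growth strings)
set_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1L))
      grow(c(prefix, v), max(maxv, v))
    invisible()
  }
  grow(integer(0), 0L)
  out
}

# maximum modularity over every partition, by exhaustive enumeration
oracle_max_modularity <- function(net) {
  n <- length(net$node_ids)
  m <- nrow(net$edges)
  ei <- match(net$edges[, 1], net$node_ids)
  ej <- match(net$edges[, 2], net$node_ids)
  deg <- tabulate(c(ei, ej), nbins = n)
  best <- -Inf
  for (mm in set_partitions(n)) {
    within <- mm[ei] == mm[ej]
    d_c <- rowsum(deg, mm)
    q <- sum(within) / m - sum((d_c / (2 * m))^2)
    if (q > best) best <- q
  }
  best
}

# Fig-2-style worked example: four classrooms of 10/25/20/16 students and
# four communities with the stated per-classroom membership counts
worked_example <- function() {
  sizes <- c(c1 = 10, c2 = 25, c3 = 20, c4 = 16)
  ids <- unlist(lapply(names(sizes), function(cl)
    sprintf("%s_%02d", cl, seq_len(sizes[[cl]]))))
  roster <- school_roster(data.frame(
    id = ids,
    classroom = rep(names(sizes), sizes),
    gender = "unknown"))
  by_cls <- split(ids, rep(names(sizes), sizes))
  communities <- list(
    chm = by_cls$c2[1:22],
    uhm = c(by_cls$c4[1:7], by_cls$c1[1:2]),
    uht = c(by_cls$c1[3:5], by_cls$c2[23:25], by_cls$c3[1:4]),
    cht = c(by_cls$c1[6:10], by_cls$c3[5:20], by_cls$c4[8:16]))
  list(roster = roster, communities = communities,
       sizes = classroom_sizes(roster))
}

# simple roster over arbitrary node ids, one classroom each
simple_roster <- function(ids, classroom, gender = "unknown",
                          kinship = NULL) {
  school_roster(data.frame(id = ids, classroom = classroom,
                           gender = gender), kinship)
}
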