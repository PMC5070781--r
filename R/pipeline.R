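#' Full friendship-network analysis
#'
#' The central driver.  Takes a nomination or friendship network plus a
#' roster, and runs the complete analysis: reciprocity filtering (if the
#' input is directed), mixed-link flagging and optional removal, the
#' full-network summary, leading-eigenvector community detection on the
#' giant component — every non-giant component (including each isolated
#' node) is kept verbatim as one community — and homogeneity/confinement
#' classification of the resulting communities.
#'
#' Network-level statistics are computed on the full analyzed network
#' (which is how isolated nodes and component counts stay reportable);
#' community statistics cover the giant component's communities together
#' with the small components.
#'
#' @param network a `nomination_network` or `friendship_network`.
#' @param roster a `school_roster` (classroom, gender, kinship).
#' @param remove_mixed drop mixed links before analysis?
#' @param threshold homogeneity/confinement threshold (default 0.60).
#' @param clustering_method `"avg_local"` or `"transitivity"`.
#' @param tol split-acceptance tolerance for [detect_communities()].
#' @return An object of class `"school_network_analysis"`: list with
#'   `network` (the analyzed `friendship_network`), `summary`
#'   (`network_summary`), `partition` (`community_partition` over all
#'   nodes), `community_summary`, `records`, `log` (character vector of
#'   decision lines) and the call.
#' @export
analyze_school_network <- function(network, roster,
                                   remove_mixed = FALSE,
                                   threshold = 0.60,
                                   clustering_method = "avg_local",
                                   tol = 1e-10) {
  stopifnot(inherits(roster, "school_roster"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  if (inherits(network, "nomination_network")) {
    say("input: directed nominations (%d nodes, %d arcs); reciprocity filter",
        n_nodes(network), n_edges(network))
    net <- symmetrize_reciprocal(network)
  } else if (inherits(network, "friendship_network")) {
    say("input: undirected friendship network (%d nodes, %d edges)",
        n_nodes(network), n_edges(network))
    net <- network
  } else stop("network must be a nomination_network or friendship_network",
              call. = FALSE)

  net <- flag_mixed_links(net, roster)
  say("mixed links flagged: %d of %d edges", mixed_count(net), n_edges(net))
  if (remove_mixed) {
    net <- remove_mixed_links(net)
    say("mixed links removed: %d edges remain", n_edges(net))
  }

  summary <- summarize_network(net, clustering_method)
  if (n_edges(net) == 0L)
    stop("analysis stage 'communities': network has no edges", call. = FALSE)

  comps <- network_components(net)
  giant_ids <- comps$members[[1L]]
  say("giant component: %d of %d nodes; %d further nontrivial component(s), %d isolated",
      length(giant_ids), n_nodes(net), comps$count_nontrivial - 1L,
      comps$isolated)

  gc_net <- induced_network(net, giant_ids)
  gc_part <- detect_communities(gc_net, tol = tol)
  for (r in seq_len(nrow(gc_part$trace)))
    say("bisection: size=%d shifted=%s dQ=%.6g accepted=%s",
        gc_part$trace$group_size[r], gc_part$trace$shifted[r],
        gc_part$trace$delta_q[r], gc_part$trace$accepted[r])

  # stitch: giant-component communities + each small component verbatim
  small <- c(comps$members[-1L],
             as.list(sort(setdiff(net$node_ids,
                                  unlist(c(comps$members))))))
  groups <- c(split(names(gc_part$assignment), gc_part$assignment), small)
  groups <- groups[order(vapply(groups, min, character(1)))]
  assignment <- integer(n_nodes(net))
  names(assignment) <- net$node_ids
  for (i in seq_along(groups)) assignment[groups[[i]]] <- i
  partition <- structure(list(assignment = assignment,
                              n_communities = length(groups),
                              Q = partition_modularity(net, assignment),
                              trace = gc_part$trace,
                              tol = tol),
                         class = "community_partition")
  say("communities: %d in giant component + %d small components = %d total",
      gc_part$n_communities, length(small), length(groups))

  csum <- community_summary(partition, net, roster, threshold,
                            clustering_method)
  structure(list(network = net,
                 summary = summary,
                 partition = partition,
                 community_summary = csum,
                 records = attr(csum, "records"),
                 log = log,
                 call = match.call()),
            class = "school_network_analysis")
}

#' @export
print.school_network_analysis <- function(x, ...) {
  cat("School friendship-network analysis\n\n")
  print(x$summary)
  cat("\n")
  print(x$partition)
  cat("\n")
  print(x$community_summary)
  invisible(x)
}

#' @export
summary.school_network_analysis <- function(object, ...) {
  print(object)
}

#' Run the pipeline from files and write all artifacts
#'
#' File-level orchestration over [analyze_school_network()]: reads the
#' network (adjacency CSV, edge-list TSV or GraphML chosen by
#' extension), the roster and the kinship table, runs the analysis, and
#' writes `summary.json`, `partition.csv`, `classification.csv`,
#' `community_summary.json`, `network.graphml` and `run_log.txt` into
#' `out_dir`.
#'
#' @param network_path path to the network file (`.csv` adjacency,
#'   `.tsv` edge list, `.graphml`).
#' @param roster_path path to the roster CSV.
#' @param kinship_path optional path to the kinship CSV.
#' @param out_dir output directory (created if needed).
#' @param directed is the input network directed nominations?  With an
#'   adjacency CSV and `directed = NA` (default) symmetry is
#'   auto-detected and the decision logged.
#' @param remove_mixed,threshold,clustering_method,tol passed through.
#' @return The `school_network_analysis`, invisibly.
#' @export
run_pipeline <- function(network_path, roster_path, kinship_path = NULL,
                         out_dir = ".", directed = NA,
                         remove_mixed = FALSE, threshold = 0.60,
                         clustering_method = "avg_local", tol = 1e-10) {
  roster <- read_roster(roster_path)
  if (!is.null(kinship_path)) roster <- read_kinship(kinship_path, roster)
  ext <- tolower(tools::file_ext(network_path))
  pre_log <- character(0)
  if (ext == "tsv") {
    network <- read_edgelist(network_path,
                             directed = isTRUE(directed) || is.na(directed),
                             nodes = roster$table$id)
  } else if (ext == "graphml") {
    network <- read_graphml(network_path)$network
  } else {
    if (is.na(directed)) {
      # auto-detect: a symmetric matrix is read as undirected
      network <- tryCatch(read_adjacency(network_path, directed = FALSE),
                          error = function(e) NULL)
      if (is.null(network)) {
        network <- read_adjacency(network_path, directed = TRUE)
        pre_log <- "adjacency auto-detect: asymmetric, read as directed"
      } else {
        pre_log <- "adjacency auto-detect: symmetric, read as undirected"
      }
    } else {
      network <- read_adjacency(network_path, directed = directed)
    }
  }
  res <- analyze_school_network(network, roster,
                                remove_mixed = remove_mixed,
                                threshold = threshold,
                                clustering_method = clustering_method,
                                tol = tol)
  res$log <- c(pre_log, res$log)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(res$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_partition(res$partition, file.path(out_dir, "partition.csv"))
  write_classification(res$records, file.path(out_dir, "classification.csv"))
  cs <- unclass(res$community_summary)
  cs$class_counts <- as.list(cs$class_counts)
  jsonlite::write_json(cs, file.path(out_dir, "community_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  labels <- stats::setNames(
    unlist(lapply(res$records, function(r)
      rep(r$class_label, r$size))),
    unlist(lapply(res$records, `[[`, "members")))
  write_network(res$network, file.path(out_dir, "network.graphml"),
                format = "graphml", roster = roster,
                partition = res$partition, labels = labels)
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(res)
}

#' Benchmark harness for deposited adjacency matrices
#'
#' Given a directory holding the deposited square adjacency matrices as
#' CSV (`E1.csv`, `E2.csv`, `E3.csv`, `E1NF.csv`, `E2NF.csv`,
#' `E3NF.csv`, `University.csv`, any subset), computes the headline
#' summary of each under both clustering definitions and, for matrices
#' with an available roster, the community count.  Symmetry is
#' auto-detected per file and recorded, since the deposit convention
#' (raw directed vs already reciprocity-filtered) is not documented.
#'
#' @param dir directory containing the matrices.
#' @param detect run community detection on each giant component?
#' @return Data frame, one row per matrix found.
#' @export
benchmark_deposited <- function(dir, detect = TRUE) {
  if (!dir.exists(dir))
    stop("deposited-data directory not found: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files))
    stop("no adjacency CSVs in ", dir, call. = FALSE)
  rows <- lapply(files, function(f) {
    net <- tryCatch(read_adjacency(f, directed = FALSE),
                    error = function(e) NULL)
    symmetric <- !is.null(net)
    if (!symmetric)
      net <- symmetrize_reciprocal(read_adjacency(f, directed = TRUE))
    s <- summarize_network(net, "avg_local")
    c_trans <- clustering_coefficient(net, "transitivity")
    n_comm <- NA_integer_
    if (detect && s$m > 0L) {
      part <- suppressWarnings(detect_communities(giant_component(net)))
      n_comm <- part$n_communities +
        (s$components - 1L) + s$isolated
    }
    data.frame(file = basename(f), symmetric_deposit = symmetric,
               n = s$n, m = s$m, connected = s$connected,
               avg_degree = s$avg_degree, density = s$density,
               clustering_avg_local = s$clustering,
               clustering_transitivity = c_trans,
               isolated = s$isolated, components = s$components,
               n_g = s$n_g, m_g = s$m_g,
               communities = n_comm)
  })
  do.call(rbind, rows)
}
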