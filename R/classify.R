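#' Community classification by homogeneity and confinement
#'
#' A community is *homogeneous* when at least a threshold fraction
#' (default 60%) of its members come from a single classroom, otherwise
#' heterogeneous.  It is *confined* when there exists a classroom at
#' least that fraction of whose students sit inside the community,
#' otherwise unconfined.  Crossing the two booleans yields four mutually
#' exclusive classes:
#'
#' * `CHm` — confined homogeneous
#' * `UHm` — unconfined homogeneous
#' * `CHt` — confined heterogeneous
#' * `UHt` — unconfined heterogeneous
#'
#' Both thresholds are inclusive ("at least 60%") and confinement
#' quantifies existentially over classrooms.  Confinement denominators
#' are full classroom sizes from the roster, not network presence.
#'
#' @name classify
NULL

#' @describeIn classify Largest classroom share of a community and
#'   whether it reaches the homogeneity threshold.
#' @param members character vector of community member ids.
#' @param roster a `school_roster`.
#' @param threshold inclusive fraction, default 0.60.
#' @return `homogeneity()`: list with `fraction` (max classroom share),
#'   `homogeneous` (logical) and `shares` (named vector of per-classroom
#'   shares of the community).
#' @export
homogeneity <- function(members, roster, threshold = 0.60) {
  stopifnot(inherits(roster, "school_roster"))
  if (!length(members)) stop("empty community", call. = FALSE)
  cls <- stats::setNames(roster$table$classroom, roster$table$id)
  mc <- cls[as.character(members)]
  if (anyNA(mc)) stop("community member missing a classroom", call. = FALSE)
  shares <- as.numeric(table(mc)) / length(members)
  names(shares) <- names(table(mc))
  frac <- max(shares)
  list(fraction = frac, homogeneous = frac >= threshold, shares = shares)
}

#' @describeIn classify Whether some classroom has at least the threshold
#'   fraction of its students inside the community.
#' @param sizes named vector of full classroom sizes (see
#'   [classroom_sizes()]); taken from the roster when `NULL`.
#' @return `confinement()`: list with `confined` (logical) and
#'   `coverage` (named vector: fraction of each represented classroom's
#'   students that are in the community).
#' @export
confinement <- function(members, roster, sizes = NULL, threshold = 0.60) {
  stopifnot(inherits(roster, "school_roster"))
  if (!length(members)) stop("empty community", call. = FALSE)
  if (is.null(sizes)) sizes <- classroom_sizes(roster)
  cls <- stats::setNames(roster$table$classroom, roster$table$id)
  mc <- cls[as.character(members)]
  if (anyNA(mc)) stop("community member missing a classroom", call. = FALSE)
  counts <- table(mc)
  denom <- sizes[names(counts)]
  if (anyNA(denom) || any(denom == 0))
    stop("classroom with unknown or zero size", call. = FALSE)
  coverage <- as.numeric(counts) / as.numeric(denom)
  names(coverage) <- names(counts)
  list(confined = any(coverage >= threshold), coverage = coverage)
}

#' @describeIn classify Build the full per-community record:
#'   composition, the two verdicts, the four-way label, and gender
#'   composition.
#' @param community integer or character community identifier.
#' @return `classify_community()`: an object of class
#'   `"community_record"`.
#' @export
classify_community <- function(members, roster, sizes = NULL,
                               threshold = 0.60, community = NA) {
  hom <- homogeneity(members, roster, threshold)
  con <- confinement(members, roster, sizes, threshold)
  label <- if (con$confined) {
    if (hom$homogeneous) "CHm" else "CHt"
  } else {
    if (hom$homogeneous) "UHm" else "UHt"
  }
  rec <- structure(list(
    community = community,
    members = sort(as.character(members)),
    size = length(members),
    classroom_counts = round(hom$shares * length(members)),
    homogeneity_fraction = hom$fraction,
    homogeneous = hom$homogeneous,
    confined = con$confined,
    coverage = con$coverage,
    class_label = label,
    gender_counts = NULL,
    single_gender = "none"), class = "community_record")
  gender_composition(rec, roster)
}

#' @describeIn classify Fill in gender counts and the single-gender
#'   verdict: `M` iff every member is male, `F` iff every member is
#'   female; any member of unknown gender disqualifies.
#' @param record a `community_record`.
#' @return `gender_composition()`: the updated record.
#' @export
gender_composition <- function(record, roster) {
  stopifnot(inherits(record, "community_record"),
            inherits(roster, "school_roster"))
  gen <- stats::setNames(roster$table$gender, roster$table$id)
  mg <- gen[record$members]
  mg[is.na(mg)] <- "unknown"
  counts <- table(factor(mg, levels = c("M", "F", "unknown")))
  record$gender_counts <- stats::setNames(as.integer(counts), names(counts))
  record$single_gender <-
    if (counts[["M"]] == record$size) "M"
    else if (counts[["F"]] == record$size) "F"
    else "none"
  record
}

#' @export
print.community_record <- function(x, ...) {
  cat(sprintf("Community %s: %d members, %s (homogeneity %.1f%%, %s)\n",
              x$community, x$size, x$class_label,
              100 * x$homogeneity_fraction,
              if (x$confined) "confined" else "unconfined"))
  invisible(x)
}

#' Classify every community of a partition
#'
#' @param partition a `community_partition` (or a named membership
#'   vector).
#' @param roster a `school_roster` covering all nodes.
#' @param threshold inclusive homogeneity/confinement threshold.
#' @return List of `community_record`s, one per community, in community
#'   order.
#' @export
classify_partition <- function(partition, roster, threshold = 0.60) {
  assignment <- if (inherits(partition, "community_partition"))
    partition$assignment else partition
  sizes <- classroom_sizes(roster)
  ids <- names(assignment)
  lapply(sort(unique(assignment)), function(cc)
    classify_community(ids[assignment == cc], roster, sizes, threshold,
                       community = cc))
}

#' Per-community structural and classification summary
#'
#' Aggregates a classified partition into one record: community count,
#' mean and population SD of community size (N_p), per-community density
#' (rho_p) and clustering (C_p), the node-weighted density rho_pp with a
#' node-weighted SD, the within-classroom link probabilities P_in/P_out
#' of the analyzed network, the class-label counts, and the number of
#' single-gender communities.  Density and clustering of a singleton
#' community are defined as 0.
#'
#' @param partition a `community_partition` or named membership vector.
#' @param net the analyzed `friendship_network`.
#' @param roster a `school_roster`.
#' @param threshold classification threshold.
#' @param clustering_method passed to [clustering_coefficient()].
#' @param sd_type `"population"` (divide by N, default) or `"sample"`.
#' @return An object of class `"community_summary"`; the per-community
#'   records are attached as attribute `"records"`.
#' @export
community_summary <- function(partition, net, roster, threshold = 0.60,
                              clustering_method = "avg_local",
                              sd_type = c("population", "sample")) {
  stopifnot(inherits(net, "friendship_network"))
  sd_type <- match.arg(sd_type)
  sdf <- if (sd_type == "population") sd_pop else stats::sd
  assignment <- if (inherits(partition, "community_partition"))
    partition$assignment else partition
  records <- classify_partition(assignment, roster, threshold)
  ids <- names(assignment)
  comms <- sort(unique(assignment))
  sizes <- integer(length(comms))
  dens <- numeric(length(comms))
  clus <- numeric(length(comms))
  for (i in seq_along(comms)) {
    sub <- induced_network(net, ids[assignment == comms[i]])
    sizes[i] <- n_nodes(sub)
    dens[i] <- if (n_nodes(sub) > 1L) net_density(sub) else 0
    clus[i] <- if (n_nodes(sub) > 0L)
      clustering_coefficient(sub, clustering_method) else 0
  }
  labels <- vapply(records, `[[`, character(1), "class_label")
  genders <- vapply(records, `[[`, character(1), "single_gender")
  lp <- classroom_link_probabilities(net, roster)
  out <- list(
    n_communities = length(comms),
    n_p_mean = mean(sizes), n_p_sd = sdf(sizes),
    rho_p_mean = mean(dens), rho_p_sd = sdf(dens),
    c_p_mean = mean(clus), c_p_sd = sdf(clus),
    rho_pp_mean = wmean(dens, sizes), rho_pp_sd = wsd_pop(dens, sizes),
    p_in = unname(lp["p_in"]), p_out = unname(lp["p_out"]),
    class_counts = stats::setNames(
      as.integer(table(factor(labels,
                              levels = c("CHm", "UHm", "CHt", "UHt")))),
      c("CHm", "UHm", "CHt", "UHt")),
    boys_only = sum(genders == "M"),
    girls_only = sum(genders == "F"))
  structure(out, class = "community_summary", records = records)
}

#' @export
print.community_summary <- function(x, ...) {
  cat("Community summary\n")
  cat(sprintf("  communities          %d\n", x$n_communities))
  cat(sprintf("  N_p  (SD)            %.2f (%.2f)\n", x$n_p_mean, x$n_p_sd))
  cat(sprintf("  rho_p (SD)           %.2f (%.2f)\n", x$rho_p_mean,
              x$rho_p_sd))
  cat(sprintf("  C_p  (SD)            %.2f (%.2f)\n", x$c_p_mean, x$c_p_sd))
  cat(sprintf("  rho_pp (SD)          %.2f (%.2f)\n", x$rho_pp_mean,
              x$rho_pp_sd))
  cat(sprintf("  P_in / P_out         %.2f / %.2f\n", x$p_in, x$p_out))
  cat(sprintf("  classes              CHm %d, UHm %d, CHt %d, UHt %d\n",
              x$class_counts[["CHm"]], x$class_counts[["UHm"]],
              x$class_counts[["CHt"]], x$class_counts[["UHt"]]))
  cat(sprintf("  single-gender        %d boys-only, %d girls-only\n",
              x$boys_only, x$girls_only))
  invisible(x)
}

#' Write classification records to CSV
#'
#' Columns: community, size, homogeneity_fraction, confined, label,
#' single_gender.
#'
#' @param records list of `community_record`s (or a `community_summary`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(records, path) {
  if (inherits(records, "community_summary"))
    records <- attr(records, "records")
  df <- data.frame(
    community = vapply(records, function(r) as.integer(r$community),
                       integer(1)),
    size = vapply(records, `[[`, integer(1), "size"),
    homogeneity_fraction = vapply(records, `[[`, numeric(1),
                                  "homogeneity_fraction"),
    confined = vapply(records, `[[`, logical(1), "confined"),
    label = vapply(records, `[[`, character(1), "class_label"),
    single_gender = vapply(records, `[[`, character(1), "single_gender"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
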