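test_that("worked example: four communities reproduce every share and label", {
  wx <- worked_example()
  r <- wx$roster
  sz <- wx$sizes
  cm <- wx$communities

  chm <- classify_community(cm$chm, r, sz)
  expect_equal(chm$class_label, "CHm")
  expect_equal(chm$homogeneity_fraction, 1.0)                 # 100%
  expect_equal(unname(chm$coverage[["c2"]]), 22 / 25)         # 88%
  expect_true(chm$confined)

  uhm <- classify_community(cm$uhm, r, sz)
  expect_equal(uhm$class_label, "UHm")
  expect_equal(uhm$homogeneity_fraction, 7 / 9)               # 77.7%
  expect_equal(unname(uhm$coverage[["c4"]]), 7 / 16)          # 43.7%
  expect_equal(unname(uhm$coverage[["c1"]]), 2 / 10)          # 20%
  expect_false(uhm$confined)

  uht <- classify_community(cm$uht, r, sz)
  expect_equal(uht$class_label, "UHt")
  expect_equal(unname(uht$coverage[c("c1", "c2", "c3")]),
               c(3 / 10, 3 / 25, 4 / 20))                     # 30, 12, 20%
  h <- homogeneity(cm$uht, r)
  expect_equal(unname(h$shares[c("c1", "c2", "c3")]),
               c(0.3, 0.3, 0.4))                              # 30, 30, 40%
  expect_false(h$homogeneous)

  cht <- classify_community(cm$cht, r, sz)
  expect_equal(cht$class_label, "CHt")
  expect_equal(unname(cht$coverage[c("c1", "c3", "c4")]),
               c(5 / 10, 16 / 20, 9 / 16))                    # 50, 80, 56.2%
  h2 <- homogeneity(cm$cht, r)
  expect_equal(unname(h2$shares[c("c1", "c3", "c4")]),
               c(5 / 30, 16 / 30, 9 / 30))                    # 16.6/53.3/30.0%
  expect_true(cht$confined)
  expect_false(h2$homogeneous)
})

test_that("60% thresholds are inclusive and errors are raised", {
  ids <- sprintf("s%02d", 1:10)
  roster <- simple_roster(ids, c(rep("A", 6), rep("B", 4)))
  # exactly 60% of the community from classroom A -> homogeneous
  comm <- c(ids[1:3], ids[7:8])   # 3 of 5 from A
  h <- homogeneity(comm, roster)
  expect_equal(h$fraction, 0.6)
  expect_true(h$homogeneous)
  # exactly 60% of classroom B inside -> confined: B has 4, need >= 2.4
  comm_b <- ids[7:9]              # 3/4 = 75%
  expect_true(confinement(comm_b, roster)$confined)
  comm_b2 <- ids[7:8]             # 2/4 = 50%
  expect_false(confinement(comm_b2, roster)$confined)

  expect_error(homogeneity(character(0), roster), "empty")
  expect_error(homogeneity("zz", roster), "classroom")
  expect_error(confinement(comm, roster, sizes = c(A = 0, B = 4)), "zero")
})

test_that("labels cross the two booleans exhaustively and exclusively", {
  ids <- sprintf("s%02d", 1:20)
  roster <- simple_roster(ids, rep(c("A", "B"), each = 10))
  combos <- list(
    CHm = ids[1:8],                 # 8/10 of A inside, 100% from A
    UHm = ids[1:3],                 # 30% of A, all from A
    CHt = c(ids[1:7], ids[11:16]),  # 70% of A covered; max share 7/13
    UHt = c(ids[1:4], ids[11:14]))  # 40% coverage both; shares 50/50
  for (lab in names(combos)) {
    rec <- classify_community(combos[[lab]], roster)
    expect_equal(rec$class_label, lab)
    expect_equal(rec$homogeneous, lab %in% c("CHm", "UHm"))
    expect_equal(rec$confined, lab %in% c("CHm", "CHt"))
  }
})

test_that("gender composition: single-gender only when unanimous and known", {
  ids <- c("b1", "b2", "b3", "g1", "g2", "u1")
  roster <- simple_roster(ids, "A",
                          gender = c("M", "M", "M", "F", "F", "unknown"))
  rec_m <- classify_community(c("b1", "b2", "b3"), roster)
  expect_equal(rec_m$single_gender, "M")
  rec_mix <- classify_community(c("b1", "b2", "g1"), roster)
  expect_equal(rec_mix$single_gender, "none")
  rec_unk <- classify_community(c("g1", "g2", "u1"), roster)
  expect_equal(rec_unk$single_gender, "none")
  rec_f <- classify_community(c("g1", "g2"), roster)
  expect_equal(rec_f$single_gender, "F")
})

test_that("a partition identical to the classrooms is all-CHm", {
  sc <- generate_school(school_config(3, 8, p_within = 1, p_between = 0,
                                      seed = 5))
  roster <- sc$roster
  truth <- setNames(as.integer(factor(roster$table$classroom)),
                    roster$table$id)
  recs <- classify_partition(truth, roster)
  labs <- vapply(recs, `[[`, character(1), "class_label")
  expect_true(all(labs == "CHm"))
  fracs <- vapply(recs, `[[`, numeric(1), "homogeneity_fraction")
  expect_true(all(fracs == 1))
})

test_that("community summary: degenerate and identity cases", {
  # disjoint triangles as communities: all densities/clusterings 1, SD 0
  net <- two_triangles_net()
  roster <- simple_roster(net$node_ids, rep(c("A", "B"), each = 3))
  part <- setNames(rep(1:2, each = 3), net$node_ids)
  cs <- community_summary(part, net, roster)
  expect_equal(cs$n_communities, 2)
  expect_equal(cs$rho_p_mean, 1)
  expect_equal(cs$rho_p_sd, 0)
  expect_equal(cs$c_p_mean, 1)
  expect_equal(cs$c_p_sd, 0)
  # equal-size communities: node-weighted density equals the plain mean
  expect_equal(cs$rho_pp_mean, cs$rho_p_mean)
  expect_equal(sum(cs$class_counts), cs$n_communities)

  # single community = whole network
  tri <- triangle_net()
  r3 <- simple_roster(tri$node_ids, "A")
  cs1 <- community_summary(setNames(rep(1, 3), tri$node_ids), tri, r3)
  expect_equal(cs1$n_p_mean, 3)
  expect_equal(cs1$rho_p_mean, net_density(tri))
})

test_that("weighted density lies between the community extremes", {
  for (seed in 1:5) {
    net <- random_connected_net(12, 0.3, seed)
    roster <- simple_roster(net$node_ids,
                            rep(c("A", "B", "C"), each = 4))
    set.seed(seed)
    part <- setNames(sample(1:3, 12, replace = TRUE), net$node_ids)
    part <- setNames(as.integer(factor(part)), names(part))
    cs <- community_summary(part, net, roster)
    dens <- vapply(sort(unique(part)), function(cc) {
      sub <- induced_network(net, names(part)[part == cc])
      if (n_nodes(sub) > 1) net_density(sub) else 0
    }, numeric(1))
    expect_gte(cs$rho_pp_mean, min(dens) - 1e-12)
    expect_lte(cs$rho_pp_mean, max(dens) + 1e-12)
  }
})

test_that("classification is invariant under relabeling and renumbering", {
  net <- random_connected_net(10, 0.35, 31)
  roster <- simple_roster(net$node_ids, rep(c("A", "B"), each = 5))
  part <- setNames(c(rep(1L, 5), rep(2L, 5)), net$node_ids)
  cs <- community_summary(part, net, roster)
  # renumber communities (2,1) -> same aggregate summary
  part2 <- setNames(c(rep(2L, 5), rep(1L, 5)), net$node_ids)
  cs2 <- community_summary(part2, net, roster)
  expect_equal(cs$class_counts, cs2$class_counts)
  expect_equal(cs$rho_p_mean, cs2$rho_p_mean)
  expect_equal(cs$n_p_sd, cs2$n_p_sd)
})

test_that("singleton communities contribute zero density and clustering", {
  net <- friendship_network(c("a", "b", "c", "d"),
                            rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  roster <- simple_roster(net$node_ids, "A")
  part <- setNames(c(1L, 1L, 1L, 2L), net$node_ids)
  cs <- community_summary(part, net, roster)
  expect_equal(cs$n_communities, 2)
  expect_equal(cs$rho_p_mean, (1 + 0) / 2)
  expect_equal(cs$c_p_mean, (1 + 0) / 2)
})

test_that("sample-SD switch changes only the dispersion estimates", {
  net <- two_triangles_net()
  roster <- simple_roster(net$node_ids, rep(c("A", "B"), each = 3))
  part <- setNames(rep(1:2, each = 3), net$node_ids)
  pop <- community_summary(part, net, roster, sd_type = "population")
  sam <- community_summary(part, net, roster, sd_type = "sample")
  expect_equal(pop$n_p_mean, sam$n_p_mean)
  expect_equal(pop$n_p_sd, 0)
  expect_equal(sam$n_p_sd, stats::sd(c(3, 3)))
})
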