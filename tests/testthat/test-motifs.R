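test_that("census matches the worked four-edge example with roles", {
  edges <- tibble::tribble(~regulator, ~target, ~edge_class,
                           "T", "M", "TMI",
                           "T", "G", "TTI",
                           "M", "G", "MTI",
                           "T", "G2", "TTI")
  cen <- census_triads(assemble_static(edges))
  expect_equal(nrow(cen), 3)
  expect_equal(sum(cen$motif_type == "ffl"), 1)
  expect_equal(sum(cen$motif_type == "fanout"), 2)
  expect_equal(sum(cen$motif_type %in% c("cascade", "fanin")), 0)
  ffl <- cen[cen$motif_type == "ffl", ]
  expect_equal(c(ffl$X, ffl$Y, ffl$Z), c("T", "M", "G"))
  # fan-out with one miRNA target puts it in the Y slot
  fo <- cen[cen$motif_type == "fanout" & cen$Y == "M", ]
  expect_equal(nrow(fo), 1)
  expect_equal(fo$Z, "G2")
  # single-edge network: no triads
  expect_equal(nrow(census_triads(assemble_static(edges[1, ]))), 0)
})

test_that("census equals the exhaustive triple oracle on random graphs", {
  for (s in 1:10) {
    g <- random_typed_digraph(25, 0.08, seed = 100 + s)
    cen <- census_triads(g)
    expect_equal(sort_tbl(census_members(cen)),
                 sort_tbl(oracle_census(g$edges, g$node_types)),
                 ignore_attr = TRUE)
    # type counts agree with the C-level triad census used for nulls
    fast <- mirdynet:::count_triads(g$edges, g$node_types$node)
    tab <- table(factor(cen$motif_type, names(fast)))
    expect_equal(unname(fast), as.numeric(tab))
  }
})

test_that("dynamic census applies induced semantics per layer", {
  edges <- tibble::tribble(~regulator, ~target, ~edge_class,
                           "TF1", "miR1", "TMI",
                           "TF1", "g1", "TTI",
                           "miR1", "g1", "MTI")
  net <- assemble_static(edges)
  de <- activity_to_de(tibble::tibble(entity = c("miR1", "g1"),
                                      occurrence = c("1111111", "1111111")))
  dyn <- build_dynamic(net, de, tf_policy = "always_active")
  # silence the miR1->g1 edge at layers 4-7: the FFL degrades to a fan-out
  dyn$edge_activity["miR1->g1", 4:7] <- FALSE
  inst <- census_dynamic(dyn)
  ffl <- inst[inst$motif_type == "ffl", ]
  fo <- inst[inst$motif_type == "fanout", ]
  expect_equal(ffl$occurrence, "1110000")
  expect_equal(ffl$persistence, 3L)
  expect_equal(fo$occurrence, "0001111")    # TF1 -> {g1} only... with miR1 gone
  expect_equal(fo$X, "TF1")
  # persistence conservation: counts over persistence classes sum to instances
  expect_equal(sum(table(inst$persistence)), nrow(inst))
})

test_that("enrichment flags planted FFLs and degenerate nulls", {
  cfg <- sim_config(seed = 2, n_tfs = 20, n_mirnas = 20, n_targets = 40,
                    n_planted_motifs = c(ffl = 15), background_density = 0.01)
  net <- simulate_network(cfg)
  enr <- motif_enrichment(net, n_random = 100, seed = 3)
  expect_gt(enr$z[enr$motif_type == "ffl"], 2)
  expect_true(all(enr$empirical_p >= 1 / 101))
  # single-edge classes admit no swaps: identical nulls, degenerate flag
  tiny <- assemble_static(tibble::tribble(~regulator, ~target, ~edge_class,
                                          "TF1", "miR1", "TMI",
                                          "miR1", "g1", "MTI"))
  enr2 <- motif_enrichment(tiny, n_random = 20, seed = 1)
  expect_true(all(enr2$degenerate))
  expect_true(all(is.nan(enr2$z)))
})

test_that("edge swapping preserves degrees, classes and simplicity", {
  g <- random_typed_digraph(20, 0.2, seed = 42)
  set.seed(1)
  sw <- mirdynet:::swap_edges_within_class(g$edges)
  expect_equal(table(sw$edge_class), table(g$edges$edge_class))
  expect_equal(sort(table(sw$regulator)), sort(table(g$edges$regulator)))
  for (cls in unique(g$edges$edge_class)) {
    expect_equal(sort(table(sw$target[sw$edge_class == cls])),
                 sort(table(g$edges$target[g$edges$edge_class == cls])))
  }
  expect_false(any(duplicated(paste(sw$regulator, sw$target))))
  expect_false(any(sw$regulator == sw$target))
})

test_that("coherence applies sign expectations along motif edges", {
  edges <- tibble::tribble(~regulator, ~target, ~edge_class,
                           "TF1", "miR1", "TMI",
                           "TF1", "g1", "TTI",
                           "miR1", "g1", "MTI")
  net <- assemble_static(edges)
  inst <- census_triads(net)
  mk_de <- function(px, py, pz) {
    tps <- default_time_points()
    tibble::tibble(entity = rep(c("TF1", "miR1", "g1"), each = 7),
                   time_point = rep(tps, 3),
                   log2fc = c(px, py, pz),
                   p = 0.01, q = 0.01, is_de = TRUE, direction = "up")
  }
  # all three share one profile: MTI pair correlates positively -> incoherent
  a <- rnorm(7)
  co1 <- pair_coherence(inst, mk_de(a, a, a), net)
  expect_false(co1$coherent)
  # oblique construction: r_xy > 0, r_xz > 0, r_yz < 0 -> coherent
  u <- c(1, -1, 1, -1, 1, -1, 1); v <- c(1, 1, -1, -1, 1, 1, -1)
  co2 <- pair_coherence(inst, mk_de(u, 0.5 * u + v, 0.5 * u - v), net)
  expect_true(co2$coherent)
  expect_gt(co2$r_xy, 0); expect_gt(co2$r_xz, 0); expect_lt(co2$r_yz, 0)
  # affine profiles give r = 1 exactly
  co3 <- pair_coherence(inst, mk_de(1:7, 2 * (1:7), 1:7), net)
  expect_equal(co3$r_xy, 1)
  # constant profile: undefined pair, NA flag
  co4 <- pair_coherence(inst, mk_de(rep(1, 7), a, -a), net)
  expect_true(is.na(co4$coherent))
})

test_that("crosstalk counts node-sharing FFL instances", {
  disjoint <- tibble::tibble(motif_type = "ffl",
                             X = c("a1", "a2"), Y = c("b1", "b2"), Z = c("c1", "c2"))
  expect_equal(crosstalk_degree(disjoint)$crosstalk, c(0L, 0L))
  shared <- tibble::tibble(motif_type = "ffl",
                           X = c("x1", "x2", "x3"), Y = "miR", Z = c("z1", "z2", "z3"))
  expect_equal(crosstalk_degree(shared)$crosstalk, c(2L, 2L, 2L))
  expect_error(crosstalk_degree(tibble::tibble(motif_type = "fanin",
                                               X = "a", Y = "b", Z = "c")),
               "FFL instances only")
})

test_that("local clustering matches closed forms and the brute-force oracle", {
  # 3-clique: everyone CC 1; star centre: CC 0
  tri <- tibble::tibble(regulator = c("a", "b", "a"), target = c("b", "c", "c"),
                        edge_class = "TTI")
  expect_equal(unname(local_clustering(tri)), c(1, 1, 1))
  star <- tibble::tibble(regulator = "hub", target = c("l1", "l2", "l3"),
                         edge_class = "TTI")
  expect_equal(local_clustering(star)[["hub"]], 0)
  for (s in 1:5) {
    g <- random_typed_digraph(20, 0.12, seed = 200 + s)
    mine <- local_clustering(g$edges, g$node_types$node)
    expect_equal(unname(mine), unname(oracle_cc(g$edges, g$node_types$node)),
                 tolerance = 1e-12)
  }
})

test_that("role CC profiles average per layer over instance occurrences", {
  des <- simulate_crosstalk_design()
  dyn <- build_dynamic(assemble_static(des$edges),
                       activity_to_de(des$activity), tf_policy = "de_only")
  inst <- census_dynamic(dyn)
  ffl <- inst[inst$motif_type == "ffl", ]
  cc <- role_cc_profile(dyn, ffl)
  ycc <- cc[cc$role == "Y", ]
  ycc <- ycc[order(ycc$persistence), ]
  # closed form: Y neighbourhood is a 2p-clique plus 7-p dangling targets
  expected <- vapply(1:7, function(p) choose(2 * p, 2) / choose(p + 7, 2), numeric(1))
  expect_equal(ycc$mean_cc, expected, tolerance = 1e-12)
  expect_equal(cc$mean_cc[cc$role == "X"], rep(1, 7))
  expect_equal(cc$mean_cc[cc$role == "Z"], rep(1, 7))
})
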