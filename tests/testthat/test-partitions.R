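test_that("partition_nmi is 1 on identical partitions and label-invariant", {
  set.seed(21)
  nodes <- paste0("v", 1:12)
  for (rep in 1:20) {
    p <- random_partition(nodes, k_max = 4)
    relab <- stats::setNames(paste0("L", p), names(p))
    expect_equal(partition_nmi(p, p), 1)
    expect_equal(partition_nmi(p, relab), 1)
    for (variant in c("min", "max", "sqrt"))
      expect_equal(partition_nmi(p, relab, normalization = variant), 1)
  }
})

test_that("partition_nmi matches the hand-computable zero case and is symmetric", {
  # P1 = {ab|cd}, P2 = {ac|bd}: the contingency table is uniform, MI = 0
  p1 <- c(a = "1", b = "1", c = "2", d = "2")
  p2 <- c(a = "1", b = "2", c = "1", d = "2")
  expect_equal(partition_nmi(p1, p2), 0)

  set.seed(22)
  nodes <- paste0("v", 1:15)
  for (rep in 1:20) {
    pa <- random_partition(nodes); pb <- random_partition(nodes)
    v <- partition_nmi(pa, pb)
    expect_equal(v, partition_nmi(pb, pa))
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_error(partition_nmi(p1, p2[1:3]), "node set")
})

test_that("partition_nmi agrees with igraph's arithmetic-mean NMI", {
  set.seed(23)
  nodes <- paste0("v", 1:30)
  for (rep in 1:25) {
    pa <- random_partition(nodes, 5); pb <- random_partition(nodes, 5)
    ours <- partition_nmi(pa, pb)
    ref <- igraph::compare(as.integer(factor(pa)), as.integer(factor(pb)),
                           method = "nmi")
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("same_partition and canonical_form agree with brute-force block comparison", {
  set.seed(24)
  nodes <- paste0("v", 1:10)
  for (rep in 1:50) {
    pa <- random_partition(nodes, 3); pb <- random_partition(nodes, 3)
    same <- brute_same_partition(pa, pb)
    expect_identical(same_partition(pa, pb), same)
    expect_identical(canonical_form(pa) == canonical_form(pb), same)
    # NMI = 1 criterion is equivalent (within floating tolerance)
    expect_identical(partition_nmi(pa, pb) >= 1 - 1e-12, same)
  }
  # single-node graph has one canonical token
  expect_equal(canonical_form(c(x = "7")), "x")
})

test_that("hub-in-clique and hub-singleton reference partitions differ", {
  refs <- rc_reference_partitions(4, 5)
  expect_false(same_partition(refs$P1, refs$P_singleton))
  expect_false(same_partition(refs$P1, refs$P2))
  # differing in one node's assignment is enough
  p <- refs$P1; p["c1_n1"] <- "2"
  expect_false(same_partition(p, refs$P1))
})

test_that("validate_partition flags the basic-violation codes", {
  g <- rc_graph(4, 5, central = TRUE)
  refs <- rc_reference_partitions(4, 5)

  # hub-singleton partition: valid, not degenerate; counts by construction
  v <- validate_partition(g, refs$P_singleton)
  expect_true(v$is_valid); expect_false(v$is_degenerate)
  expect_equal(v$intra_edges, 40)   # 4 * choose(5,2)
  expect_equal(v$inter_edges, 8)    # 4 ring + 4 hub edges
  expect_equal(v$intra_edges + v$inter_edges, igraph::ecount(g))

  one <- stats::setNames(rep("1", 21), igraph::V(g)$name)
  v1 <- validate_partition(g, one)
  expect_false(v1$is_valid)
  expect_equal(v1$reasons, "ALL_ONE_COMMUNITY")

  singl <- stats::setNames(as.character(1:21), igraph::V(g)$name)
  vs <- validate_partition(g, singl)
  expect_false(vs$is_valid)
  expect_true("ALL_SINGLETONS" %in% vs$reasons)
  expect_true(vs$is_degenerate)     # every edge is inter-community

  # strand two non-adjacent members of clique 2 into community 1
  p <- rc_reference_partitions(4, 5, central = FALSE)$P0
  p[c("c2_n4", "c2_n5")] <- "1"     # not adjacent to clique 1's nodes
  g0 <- rc_graph(4, 5, central = FALSE)
  vd <- validate_partition(g0, p)
  expect_true("DISCONNECTED_COMMUNITY" %in% vd$reasons)
  expect_false(vd$is_valid)
})

test_that("connected components are never flagged as disconnected; degeneracy can be weighted", {
  set.seed(25)
  g <- erdos_renyi_graph(40, 0.05, seed = 3)
  comp <- igraph::components(g)$membership
  p <- stats::setNames(as.character(comp), igraph::V(g)$name)
  v <- validate_partition(g, p)
  expect_false("DISCONNECTED_COMMUNITY" %in% v$reasons)
  expect_equal(v$intra_edges + v$inter_edges, igraph::ecount(g))

  # weighted degeneracy: heavy inter edge flips the verdict
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "c", "a"), to = c("b", "d", "c"),
               weight = c(1, 1, 10)), directed = FALSE)
  p2 <- c(a = "1", b = "1", c = "2", d = "2")
  expect_false(validate_partition(g2, p2)$is_degenerate)
  expect_true(validate_partition(g2, p2, weighted = TRUE)$is_degenerate)
})
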