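test_that("a single partition gives its 0/1 block matrix", {
  p <- c(a = "1", b = "1", c = "2", d = "2", e = "3")
  am <- agreement_matrix(list(p), probs = 1)
  expect_true(all(am %in% c(0, 1)))
  expect_equal(unname(diag(am)), rep(1, 5))
  expect_equal(am["a", "b"], 1)
  expect_equal(am["a", "c"], 0)
  expect_true(isSymmetric(unclass(am)))
  # single-partition space: co-occurring nodes score 1; the singleton
  # community never co-occurs with anyone and gets a flagged NA profile
  prof <- outlier_profiles(am)
  expect_equal(prof$gamma_bar_plus, c(1, 1, 1, 1, NA))
})

test_that("the RC+C hub has 0.25 agreement with clique nodes, clique pairs have 1", {
  refs <- rc_reference_partitions(4, 5)
  am <- agreement_matrix(refs[paste0("P", 1:4)], probs = rep(0.25, 4))

  clique_nodes <- setdiff(rownames(am), "centre")
  expect_equal(unname(unclass(am)["centre", clique_nodes]),
               rep(0.25, 20))
  for (i in 1:4) {
    members <- paste0("c", i, "_n", 1:5)
    block <- unclass(am)[members, members]
    expect_true(all(block == 1))
    others <- setdiff(clique_nodes, members)
    expect_true(all(unclass(am)[members, others] == 0))
  }

  prof <- outlier_profiles(am, threshold = 0.5)
  hub <- prof[prof$node == "centre", ]
  expect_equal(hub$gamma_bar_plus, 0.25)
  expect_equal(hub$n_nonzero_partners, 20)
  expect_true(hub$is_outlier)
  cl <- prof[prof$node != "centre", ]
  # all-partner mean mixes 4 in-clique 1.0s with the hub's 0.25
  expect_equal(cl$gamma_bar_plus, rep((4 * 1 + 0.25) / 5, 20))
  # partner-restricted statistic: clique members score 1 relative to each other
  expect_equal(cl$gamma_bar_top, rep(1, 20))
  expect_false(any(cl$is_outlier))
})

test_that("a node split across two equiprobable partitions scores 0.5 to both blocks", {
  p1 <- c(a = "1", b = "1", x = "1", c = "2", d = "2")
  p2 <- c(a = "1", b = "1", x = "2", c = "2", d = "2")
  am <- agreement_matrix(list(p1, p2), probs = c(0.5, 0.5))
  expect_equal(am["x", "a"], 0.5)
  expect_equal(am["x", "c"], 0.5)
  expect_equal(am["a", "b"], 1)
  expect_equal(am["a", "c"], 0)
})

test_that("agreement matches the brute-force double sum on random small cases", {
  brute <- function(partitions, probs) {
    nodes <- names(partitions[[1]])
    out <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    for (u in nodes) for (v in nodes) {
      s <- 0
      for (i in seq_along(partitions)) {
        pi <- partitions[[i]]
        s <- s + probs[i] * as.numeric(pi[[u]] == pi[[v]])
      }
      out[u, v] <- s
    }
    out
  }
  set.seed(51)
  for (rep in 1:100) {
    n <- sample(3:6, 1)
    nodes <- paste0("v", seq_len(n))
    np <- sample(1:3, 1)
    partitions <- replicate(np, random_partition(nodes, 3), simplify = FALSE)
    w <- stats::runif(np); probs <- w / sum(w)
    am <- agreement_matrix(partitions, probs = probs)
    expect_equal(bare(am), brute(partitions, probs), tolerance = 1e-15)
  }
})

test_that("agreement is linear in the probability weights and permutation-equivariant", {
  set.seed(52)
  nodes <- paste0("v", 1:8)
  for (rep in 1:50) {
    pa <- replicate(2, random_partition(nodes), simplify = FALSE)
    pb <- replicate(2, random_partition(nodes), simplify = FALSE)
    wa <- 0.3; wb <- 0.7
    joint <- agreement_matrix(c(pa, pb),
                              probs = c(rep(wa / 2, 2), rep(wb / 2, 2)))
    ma <- agreement_matrix(pa, probs = c(0.5, 0.5))
    mb <- agreement_matrix(pb, probs = c(0.5, 0.5))
    expect_equal(bare(joint), wa * bare(ma) + wb * bare(mb),
                 tolerance = 1e-12)

    # permuting the node order permutes rows/columns identically
    perm <- sample(nodes)
    mp <- agreement_matrix(lapply(pa, function(p) p[perm]),
                           probs = c(0.5, 0.5))
    expect_equal(bare(mp), bare(ma)[perm, perm])
  }
})

test_that("degenerate all-singleton spaces are flagged, not an error", {
  p <- c(a = "1", b = "2", c = "3")
  am <- agreement_matrix(list(p), probs = 1)
  prof <- outlier_profiles(am)
  expect_true(all(is.na(prof$gamma_bar_plus)))
  expect_equal(prof$n_nonzero_partners, rep(0, 3))
  expect_false(any(prof$is_outlier))
})

test_that("probs are validated and written matrices round-trip", {
  p <- c(a = "1", b = "1", c = "2")
  expect_error(agreement_matrix(list(p), probs = c(0.5, 0.5)), "one weight")
  expect_error(agreement_matrix(list(p), probs = 0.9), "sum to 1")
  expect_error(agreement_matrix(list(p, c(a = "1", z = "2", c = "1")),
                                probs = c(0.5, 0.5)), "node set")

  am <- agreement_matrix(list(p), probs = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_agreement(am, f)
  d <- utils::read.csv(f, row.names = 1)
  expect_equal(as.matrix(d), bare(am))
  # sparse triplet form above the size threshold
  write_agreement(am, f, sparse_threshold = 2)
  d2 <- utils::read.csv(f)
  expect_equal(names(d2), c("u", "v", "gamma"))
  expect_equal(nrow(d2), 1)   # only the a-b pair is non-zero off-diagonal
})
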