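# Shared fixtures and independent oracles for the test suite.

rc_graph <- function(nc = 4, cs = 5, central = TRUE) {
  ring_of_cliques(nc, cs, central = central)
}

triangle_graph <- function() {
  igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"), weight = 1),
    directed = FALSE)
}

# Random partition of a node set into at most k_max blocks.
random_partition <- function(nodes, k_max = 4) {
  labs <- sample(seq_len(k_max), length(nodes), replace = TRUE)
  stats::setNames(as.character(labs), nodes)
}

# Independent Beta quantile oracle: numerical integration of the density,
# inverted by root finding (no use of qbeta).
beta_quantile_oracle <- function(q, a, b) {
  cdf <- function(x) stats::integrate(function(u) stats::dbeta(u, a, b),
                                      0, x, rel.tol = 1e-12)$value
  stats::uniroot(function(x) cdf(x) - q, c(1e-12, 1 - 1e-12),
                 tol = 1e-12)$root
}

# Brute-force set-partition equality: compare block families directly.
brute_same_partition <- function(p1, p2) {
  blocks <- function(p) {
    b <- lapply(split(names(p), p), sort)
    b[order(vapply(b, `[`, character(1), 1))]
  }
  identical(unname(blocks(p1)), unname(blocks(p2[names(p1)])))
}

# Mock adapters for exploration fixtures ------------------------------------

# Always the same partition, whatever the input order.
constant_adapter <- function(p) {
  community_adapter(function(g) p[igraph::V(g)$name], name = "mock-constant",
                    stochastic = FALSE)
}

# Draws uniformly among a fixed set of distinct partitions.
uniform_adapter <- function(partitions) {
  community_adapter(function(g) {
    p <- partitions[[sample.int(length(partitions), 1)]]
    p[igraph::V(g)$name]
  }, name = "mock-uniform")
}

# A fresh, distinct, *valid* partition at every call on a ring-of-cliques
# graph: the clique partition with one clique split into a nonempty proper
# subset and its complement (both complete, hence connected). The counter
# enumerates (clique, subset) pairs, so partitions stay distinct as long as
# the call count does not exceed nc * (2^(cs-1) - 1).
novel_adapter <- function() {
  i <- 0
  community_adapter(function(g) {
    i <<- i + 1
    nodes <- igraph::V(g)$name
    clique <- sub("^c(\\d+)_n\\d+$", "\\1", nodes)
    member <- suppressWarnings(as.integer(sub("^c\\d+_n(\\d+)$", "\\1", nodes)))
    is_clique <- !is.na(member)
    nc <- max(as.integer(clique[is_clique]))
    cs <- max(member[is_clique])
    fam <- 2L^(cs - 1L) - 1L
    idx <- (i - 1) %% (nc * fam)
    j <- idx %/% fam + 1L
    s <- idx %% fam + 1L
    labs <- ifelse(is_clique, clique, "centre")
    in_split <- is_clique & clique == as.character(j) & member < cs &
      bitwAnd(s, bitwShiftL(1L, member - 1L)) > 0
    labs[in_split] <- "split"
    stats::setNames(labs, nodes)
  }, name = "mock-novel")
}

# Always returns the all-one-community (invalid) partition.
invalid_adapter <- function() {
  community_adapter(function(g)
    stats::setNames(rep("1", igraph::vcount(g)), igraph::V(g)$name),
    name = "mock-invalid", stochastic = FALSE)
}

# Deterministic but order-sensitive: the community split depends only on the
# storage order of the nodes, not on their identity.
order_sensitive_adapter <- function() {
  community_adapter(function(g) {
    nodes <- igraph::V(g)$name   # storage order
    half <- ceiling(length(nodes) / 2)
    stats::setNames(as.character(as.integer(seq_along(nodes) <= half)), nodes)
  }, name = "mock-order", stochastic = FALSE)
}

# Deterministic, order-sensitive, and benchmark-aware: assigns the hub to the
# clique of the storage-first clique node, mimicking a biased deterministic
# algorithm on RC+C.
biased_rc_adapter <- function() {
  community_adapter(function(g) {
    nodes <- igraph::V(g)$name
    clique <- sub("^c(\\d+)_.*$", "\\1", nodes)
    first_clique <- clique[nodes != "centre"][1]
    stats::setNames(ifelse(nodes == "centre", first_clique, clique), nodes)
  }, name = "mock-biased", stochastic = FALSE)
}

# Strip the agreement-matrix class/metadata for raw matrix comparisons.
bare <- function(m) {
  m <- unclass(m)
  attr(m, "probs") <- NULL
  attr(m, "n_solutions") <- NULL
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
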