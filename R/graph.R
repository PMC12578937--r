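#' Validate a graph for solution-space analysis
#'
#' The package works on undirected, simple (no loops, no multi-edges),
#' optionally weighted graphs with unique character node names. This helper
#' checks those invariants and returns the graph invisibly, so it can be used
#' as a guard at function entry.
#'
#' @param g An [igraph::igraph] object.
#' @return `g`, invisibly.
#' @export
check_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop_input("`g` must be an igraph object")
  if (igraph::is_directed(g)) stop_input("directed graphs are not supported")
  if (igraph::vcount(g) < 1L) stop_input("graph must have at least one node")
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyNA(nm) || anyDuplicated(nm))
    stop_input("graph nodes must carry unique, non-missing names")
  if (any(igraph::which_loop(g))) stop_input("self-loops are not supported")
  if (any(igraph::which_multiple(g))) stop_input("duplicate edges are not supported")
  w <- igraph::E(g)$weight
  if (!is.null(w) && (anyNA(w) || any(w <= 0)))
    stop_input("edge weights must be positive")
  invisible(g)
}

node_names <- function(g) igraph::V(g)$name

# Build an undirected named graph from an edge data frame (from, to, weight)
# and an explicit node order.
graph_from_edges <- function(edges, nodes) {
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes,
                                                      stringsAsFactors = FALSE))
}

#' Ring-of-cliques benchmark generator
#'
#' Generates a ring of `n_cliques` complete subgraphs of `clique_size` nodes,
#' with consecutive cliques joined by a single edge so the cliques form one
#' cycle. With `central = TRUE` an extra hub node (`"centre"`) is attached to
#' every clique by exactly one edge, creating a structural outlier whose
#' community membership is ambiguous: the graph then admits one symmetric
#' partition per clique (hub absorbed into that clique) plus the partition
#' isolating the hub as a singleton community.
#'
#' For `n_cliques = 2` a cycle would duplicate the connecting edge, so the two
#' cliques are joined by exactly one edge.
#'
#' Node names are `"c<i>_n<j>"` for member `j` of clique `i`, and `"centre"`
#' for the hub. The generator is deterministic. All edges carry weight 1.
#'
#' @param n_cliques Number of cliques (>= 2).
#' @param clique_size Nodes per clique (>= 3).
#' @param central Attach a central hub node connected once to each clique
#'   (to its lowest-index member)?
#' @return An undirected, named [igraph::igraph].
#' @examples
#' g <- ring_of_cliques(4, 5, central = TRUE)
#' igraph::vcount(g)  # 21
#' igraph::ecount(g)  # 48
#' @export
ring_of_cliques <- function(n_cliques, clique_size, central = FALSE) {
  if (!is.numeric(n_cliques) || n_cliques < 2)
    stop_input("`n_cliques` must be an integer >= 2")
  if (!is.numeric(clique_size) || clique_size < 3)
    stop_input("`clique_size` must be an integer >= 3")
  nc <- as.integer(n_cliques)
  cs <- as.integer(clique_size)

  member <- function(i, j) paste0("c", i, "_n", j)
  nodes <- as.vector(vapply(seq_len(nc), function(i) member(i, seq_len(cs)),
                            character(cs)))
  if (central) nodes <- c(nodes, "centre")

  intra <- do.call(rbind, lapply(seq_len(nc), function(i) {
    t(utils::combn(member(i, seq_len(cs)), 2L))
  }))
  ring <- if (nc == 2L) {
    cbind(member(1L, 1L), member(2L, 2L))
  } else {
    do.call(rbind, lapply(seq_len(nc), function(i) {
      cbind(member(i, 1L), member(i %% nc + 1L, 2L))
    }))
  }
  edges <- rbind(intra, ring)
  if (central) {
    edges <- rbind(edges, cbind("centre", member(seq_len(nc), 1L)))
  }
  edges <- data.frame(from = edges[, 1L], to = edges[, 2L], weight = 1,
                      stringsAsFactors = FALSE)
  check_graph(graph_from_edges(edges, nodes))
}

#' Erdős–Rényi random graph
#'
#' Samples a G(n, p) graph with named nodes `"v1"..."vn"` and unit edge
#' weights. Used as a null model: community detection on such graphs tends to
#' produce a Sparse solution space (many mutually dissimilar partitions).
#'
#' @param n Number of nodes (>= 1).
#' @param p Edge probability in \[0, 1\].
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return An undirected, named [igraph::igraph].
#' @export
erdos_renyi_graph <- function(n, p, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop_input("`n` must be >= 1")
  if (!is.numeric(p) || p < 0 || p > 1) stop_input("`p` must be in [0, 1]")
  g <- with_seed(seed, igraph::sample_gnp(as.integer(n), p, directed = FALSE))
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  if (igraph::ecount(g) > 0) igraph::E(g)$weight <- 1
  check_graph(g)
}

#' Information-preserving permutation of a graph's input ordering
#'
#' Returns the same abstract graph with its storage order randomised: the node
#' list is reordered by a uniform random permutation, the edge list is
#' independently shuffled, and each edge's endpoint order is swapped with
#' probability 1/2. Node names, adjacency and weights are untouched, so every
#' order-insensitive graph statistic (degree sequence, triangle count,
#' modularity of a given partition, ...) is identical.
#'
#' Order-sensitive community-detection algorithms generally return different
#' partitions on the permuted graph; order-invariant ones are statistically
#' indistinguishable across permutations. Comparing the two regimes is the
#' operational test for input-ordering bias.
#'
#' @param g An undirected named [igraph::igraph].
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A graph equal to `g` up to storage order.
#' @export
permute_graph <- function(g, seed = NULL) {
  check_graph(g)
  with_seed(seed, {
    nodes <- node_names(g)
    new_order <- sample(nodes)
    edges <- igraph::as_data_frame(g, what = "edges")
    if (nrow(edges) > 0) {
      edges <- edges[sample.int(nrow(edges)), , drop = FALSE]
      swap <- stats::runif(nrow(edges)) < 0.5
      tmp <- edges$from[swap]
      edges$from[swap] <- edges$to[swap]
      edges$to[swap] <- tmp
      rownames(edges) <- NULL
    }
    graph_from_edges(edges, new_order)
  })
}
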