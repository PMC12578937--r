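#' Partitions of a graph's node set
#'
#' A partition is represented as a named vector: names are node identifiers,
#' values are community labels (labels are opaque; only the induced set
#' partition matters). `as_partition()` validates the representation.
#'
#' @param x Named vector of community labels.
#' @param nodes Optional node set the partition must cover exactly.
#' @return The validated partition (labels coerced to character).
#' @export
as_partition <- function(x, nodes = NULL) {
  nm <- names(x)
  if (is.null(nm) || anyNA(nm) || anyDuplicated(nm))
    stop_input("a partition must be a vector with unique node names")
  if (anyNA(x)) stop_input("partition labels must not be missing")
  if (!is.null(nodes)) {
    if (!setequal(nm, nodes))
      stop_input("partition is not defined on the expected node set")
    x <- x[match(nodes, nm)]
  }
  stats::setNames(as.character(x), names(x))
}

# Recode labels to canonical integers 0..k-1 in order of first appearance.
canonical_labels <- function(p) {
  stats::setNames(match(p, unique(p)) - 1L, names(p))
}

communities_of <- function(p) split(names(p), p)

#' Number of communities in a partition
#' @param p A partition (named label vector).
#' @export
n_communities <- function(p) length(unique(as_partition(p)))

#' Canonical form of a partition
#'
#' A string token that is identical for two partitions if and only if they
#' induce the same set partition, regardless of label names. The token is the
#' full sorted-block representation (no hashing), so equality is exact.
#'
#' @param p A partition (named label vector).
#' @return A character scalar.
#' @export
canonical_form <- function(p) {
  p <- as_partition(p)
  blocks <- vapply(communities_of(p),
                   function(s) paste(sort(s), collapse = ","), character(1))
  paste(sort(unname(blocks)), collapse = "|")
}

#' Exact partition equality
#'
#' `TRUE` iff the two partitions induce identical set partitions. This is the
#' uniqueness criterion of the exploration loop: it is equivalent to
#' NMI = 1 but immune to floating-point error.
#'
#' @param p1,p2 Partitions on the same node set.
#' @export
same_partition <- function(p1, p2) {
  p1 <- as_partition(p1)
  p2 <- as_partition(p2, nodes = names(p1))
  canonical_form(p1) == canonical_form(p2)
}

#' Normalised Mutual Information between two partitions
#'
#' Label-permutation-invariant similarity in \[0, 1\]; equals 1 iff the two
#' partitions are identical as set partitions. The mutual information of the
#' label contingency table is normalised, by default, by the arithmetic mean
#' of the two label entropies (the Danon convention); `min`, `max` and `sqrt`
#' normalisations are also available. All variants agree on the NMI = 1
#' predicate used for uniqueness matching.
#'
#' If both partitions are trivial (zero entropy) the value is 1 when they are
#' identical and 0 otherwise.
#'
#' @param p1,p2 Partitions on the same node set.
#' @param normalization Entropy normalisation variant.
#' @return A number in \[0, 1\].
#' @export
partition_nmi <- function(p1, p2,
                          normalization = c("arithmetic", "min", "max", "sqrt")) {
  normalization <- match.arg(normalization)
  p1 <- as_partition(p1)
  p2 <- as_partition(p2, nodes = names(p1))

  n <- length(p1)
  tab <- table(p1, p2)
  joint <- tab / n
  pr <- rowSums(joint)
  pc <- colSums(joint)

  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(pr, pc)[nz]))
  h1 <- -sum(pr[pr > 0] * log(pr[pr > 0]))
  h2 <- -sum(pc[pc > 0] * log(pc[pc > 0]))

  denom <- switch(normalization,
                  arithmetic = (h1 + h2) / 2,
                  min = min(h1, h2),
                  max = max(h1, h2),
                  sqrt = sqrt(h1 * h2))
  if (denom <= .Machine$double.eps) {
    return(as.numeric(same_partition(p1, p2)))
  }
  min(max(mi / denom, 0), 1)
}

#' Validity and degeneracy checks for a partition
#'
#' A partition fails basic community requirements when all nodes fall in one
#' community (`k = 1`), every node is a singleton (`k = n_v`), or some
#' community with two or more nodes induces a disconnected subgraph. These
#' make the partition invalid. Independently, a partition is *degenerate*
#' when it has more inter-community than intra-community edges, contradicting
#' the definition of a community; by default edges are counted unweighted
#' (set `weighted = TRUE` to compare summed weights).
#'
#' Singleton communities are connected by convention. Intra- and
#' inter-community edge counts always sum to the edge count of the graph.
#'
#' @param g The graph.
#' @param p A partition of `g`'s nodes.
#' @param weighted Compare summed edge weights instead of edge counts in the
#'   degeneracy check?
#' @return An object of class `"validity_report"`: a list with `is_valid`,
#'   `is_degenerate`, `reasons` (character codes), `k`, `intra_edges`,
#'   `inter_edges`, and `community_connected` (named logical).
#' @export
validate_partition <- function(g, p, weighted = FALSE) {
  check_graph(g)
  p <- as_partition(p, nodes = node_names(g))
  k <- length(unique(p))
  n_v <- igraph::vcount(g)

  reasons <- character(0)
  if (k == 1L) reasons <- c(reasons, "ALL_ONE_COMMUNITY")
  if (k == n_v && n_v > 1L) reasons <- c(reasons, "ALL_SINGLETONS")

  comms <- communities_of(p)
  connected <- vapply(comms, function(members) {
    if (length(members) < 2L) return(TRUE)
    igraph::is_connected(igraph::induced_subgraph(g, members))
  }, logical(1))
  if (!all(connected)) reasons <- c(reasons, "DISCONNECTED_COMMUNITY")

  ends <- igraph::as_data_frame(g, what = "edges")
  same <- if (nrow(ends) > 0) p[ends$from] == p[ends$to] else logical(0)
  if (weighted) {
    w <- ends$weight %||% rep(1, nrow(ends))
    intra <- sum(w[same]); inter <- sum(w[!same])
  } else {
    intra <- sum(same); inter <- sum(!same)
  }
  degenerate <- inter > intra
  if (degenerate) reasons <- c(reasons, "INTER_GT_INTRA")

  structure(list(
    is_valid = !any(reasons %in% c("ALL_ONE_COMMUNITY", "ALL_SINGLETONS",
                                   "DISCONNECTED_COMMUNITY")),
    is_degenerate = degenerate,
    reasons = reasons,
    k = k,
    intra_edges = intra,
    inter_edges = inter,
    community_connected = connected
  ), class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("Partition validity report\n")
  cat("  communities (k):", x$k, "\n")
  cat("  intra / inter edges:", x$intra_edges, "/", x$inter_edges, "\n")
  cat("  valid:", x$is_valid, " degenerate:", x$is_degenerate, "\n")
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}
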