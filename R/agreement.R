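#' Pairwise agreement matrix of a solution space
#'
#' The agreement matrix is the probability-weighted co-classification
#' frequency of every node pair across the solution space: entry
#' `gamma[u, v] = sum_i p_i * [u and v share a community in partition i]`.
#' It is symmetric, with entries in \[0, 1\] and a unit diagonal (up to the
#' normalisation of `probs`). Nodes that always travel together have entries
#' of 1; pairs that never co-occur have entries of exactly 0.
#'
#' @param x A `"solution_space"` object (probabilities taken from the
#'   posterior means), or a list of partitions on a common node set.
#' @param probs For the list method: nonnegative weights, one per partition,
#'   summing to 1 (within 1e-9).
#' @param ... Unused.
#' @return An object of class `"agreement_matrix"`: a symmetric numeric
#'   matrix with node names as dimnames and attributes `probs` and
#'   `n_solutions`.
#' @examples
#' g <- ring_of_cliques(4, 5, central = TRUE)
#' refs <- rc_reference_partitions(4, 5)
#' am <- agreement_matrix(refs[paste0("P", 1:4)], probs = rep(0.25, 4))
#' am["centre", "c1_n1"]  # 0.25
#' @export
agreement_matrix <- function(x, ...) UseMethod("agreement_matrix")

#' @rdname agreement_matrix
#' @export
agreement_matrix.solution_space <- function(x, ...) {
  post <- posterior(x$model)
  agreement_matrix(x$solutions, probs = post$mean)
}

#' @rdname agreement_matrix
#' @export
agreement_matrix.list <- function(x, probs, ...) {
  if (length(x) == 0L) stop_input("need at least one partition")
  if (length(probs) != length(x))
    stop_input("`probs` must have one weight per partition")
  if (any(probs < 0)) stop_input("`probs` must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-9)
    stop_input("`probs` must sum to 1")
  first <- as_partition(x[[1L]])
  nodes <- names(first)
  gamma <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
  for (i in seq_along(x)) {
    p <- as_partition(x[[i]], nodes = nodes)
    gamma <- gamma + probs[i] * outer(p, p, `==`)
  }
  structure(gamma, class = c("agreement_matrix", class(gamma)),
            probs = probs, n_solutions = length(x))
}

#' @export
print.agreement_matrix <- function(x, digits = 3, max_show = 10, ...) {
  n <- nrow(x)
  cat("Pairwise agreement matrix:", n, "nodes,",
      attr(x, "n_solutions"), "weighted partitions\n")
  show <- seq_len(min(n, max_show))
  print(round(unclass(x)[show, show, drop = FALSE], digits))
  if (n > max_show) cat("... (", n - max_show, " more nodes)\n", sep = "")
  invisible(x)
}

#' Minimal heatmap of an agreement matrix
#' @param x An `"agreement_matrix"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.agreement_matrix <- function(x, ...) {
  n <- nrow(x)
  graphics::image(seq_len(n), seq_len(n), unclass(x)[, n:1, drop = FALSE],
                  zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, at = seq_len(n), labels = rownames(x), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(x)), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}

#' Per-node agreement profiles and outlier scores
#'
#' For each node `v` the outlier score is the mean of the non-zero,
#' off-diagonal entries of its row of the agreement matrix (zero entries mark
#' pairs that never co-occur and are excluded). Stable nodes score close to
#' 1 — they consistently appear with the same companions — while nodes whose
#' community membership shifts across the solution space score low. A second
#' statistic restricts the mean to the node's most-agreeing partners (those
#' at its maximal entry), the "relative to each other" reading under which
#' members of a stable block score exactly 1.
#'
#' @param m An `"agreement_matrix"`.
#' @param threshold Score below which a node is flagged as an outlier
#'   (default 0.5; reported alongside, never silently applied).
#' @return A data frame with one row per node: `node`, `gamma_bar_plus`
#'   (mean non-zero agreement; `NA` when the node never co-occurs with any
#'   other node), `gamma_bar_top` (mean over maximal-agreement partners),
#'   `n_nonzero_partners`, `is_outlier`, plus a `threshold` attribute.
#' @export
outlier_profiles <- function(m, threshold = 0.5) {
  stopifnot(inherits(m, "agreement_matrix"))
  if (threshold <= 0 || threshold >= 1)
    stop_input("`threshold` must be in (0, 1)")
  nodes <- rownames(m)
  g <- unclass(m)
  rows <- lapply(seq_along(nodes), function(i) {
    off <- g[i, -i]
    nz <- off[off > 0]
    gbar <- if (length(nz)) mean(nz) else NA_real_
    gtop <- if (length(nz)) mean(nz[nz == max(nz)]) else NA_real_
    data.frame(node = nodes[i],
               gamma_bar_plus = gbar,
               gamma_bar_top = gtop,
               n_nonzero_partners = length(nz),
               is_outlier = !is.na(gbar) && gbar < threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Write an agreement matrix to CSV
#'
#' Small matrices are written dense (header row/column of node names); above
#' `sparse_threshold` nodes a sparse triplet format (`u,v,gamma`) containing
#' only the non-zero upper-triangle entries is used.
#'
#' @param m An `"agreement_matrix"`.
#' @param path Output path.
#' @param sparse_threshold Node count above which the sparse format is used.
#' @export
write_agreement <- function(m, path, sparse_threshold = 200) {
  stopifnot(inherits(m, "agreement_matrix"))
  n <- nrow(m)
  if (n <= sparse_threshold) {
    utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  } else {
    idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
    utils::write.csv(data.frame(u = rownames(m)[idx[, 1]],
                                v = colnames(m)[idx[, 2]],
                                gamma = m[idx]),
                     path, row.names = FALSE)
  }
  invisible(path)
}
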