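#' Community-detection adapters
#'
#' An adapter wraps a community-detection algorithm behind a uniform
#' interface: called on a graph, it returns a partition (named label vector)
#' on exactly that graph's nodes. Adapters carry metadata used by the
#' exploration and reporting layers: a display name, whether the algorithm is
#' stochastic given a fixed input order, and whether it can assign a single
#' node to its own community.
#'
#' @param fn A function `graph -> partition` (named label vector).
#' @param name Display name.
#' @param params Named list of algorithm parameters, recorded in reports.
#' @param stochastic Does the algorithm randomise given a fixed input order?
#' @param can_singleton Can it produce single-node communities?
#' @return An object of class `"community_adapter"`.
#' @export
community_adapter <- function(fn, name, params = list(), stochastic = TRUE,
                              can_singleton = TRUE) {
  stopifnot(is.function(fn), is.character(name))
  structure(list(fn = fn, name = name, params = params,
                 stochastic = stochastic, can_singleton = can_singleton),
            class = "community_adapter")
}

#' @export
print.community_adapter <- function(x, ...) {
  cat("Community-detection adapter:", x$name, "\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  cat("  stochastic:", x$stochastic, " can_singleton:", x$can_singleton, "\n")
  invisible(x)
}

# Run an adapter and enforce the partition contract.
run_adapter <- function(adapter, g) {
  stopifnot(inherits(adapter, "community_adapter"))
  p <- adapter$fn(g)
  p <- tryCatch(as_partition(p, nodes = node_names(g)),
                error = function(e)
                  stop_input("adapter '", adapter$name,
                             "' violated the partition contract: ",
                             conditionMessage(e)))
  p
}

#' Built-in adapters for the igraph algorithms
#'
#' Wraps the six classical algorithms as shipped by igraph: Edge Betweenness
#' (`"eb"`), Louvain (`"lv"`), Leiden (`"ld"`), Label Propagation (`"lp"`),
#' Infomap (`"im"`) and Walktrap (`"wt"`). Algorithm parameters default to
#' the library defaults; the commonly tuned ones are exposed (`resolution`
#' for Louvain/Leiden, `steps` for Walktrap) and any extra `...` arguments
#' are passed through to the underlying `igraph::cluster_*` call.
#'
#' Algorithms returning dendrograms (Edge Betweenness, Walktrap) are cut at
#' igraph's default optimal-modularity cut. Edge Betweenness recomputes edge
#' betweenness after every removal and does not scale: a node-count guard
#' (default 500) emits a warning when exceeded.
#'
#' Stochasticity given a fixed input order, and the ability to isolate a
#' single node in its own community, vary by algorithm and library version;
#' the metadata recorded here reflects the wrapped igraph implementations.
#'
#' @param name Algorithm code (case-insensitive): eb, lv, ld, lp, im, wt.
#' @param resolution Resolution parameter for Louvain/Leiden.
#' @param steps Random-walk length for Walktrap.
#' @param eb_guard Node count above which Edge Betweenness warns.
#' @param ... Further arguments for the underlying `igraph::cluster_*` call.
#' @return A [community_adapter()].
#' @examples
#' g <- ring_of_cliques(4, 5, central = TRUE)
#' lp <- builtin_adapter("lp")
#' set.seed(1)
#' table(lp$fn(g))
#' @export
builtin_adapter <- function(name, resolution = NULL, steps = NULL,
                            eb_guard = 500, ...) {
  code <- toupper(name)
  extra <- list(...)
  memb <- function(cl) {
    m <- igraph::membership(cl)
    stats::setNames(as.character(m), names(m))
  }
  params <- extra
  fn <- switch(code,
    EB = function(g) {
      if (igraph::vcount(g) > eb_guard)
        warning("Edge Betweenness on ", igraph::vcount(g),
                " nodes may be computationally infeasible", call. = FALSE)
      # modularity treats weights as similarities, edge betweenness as
      # distances; with unit or similarity weights the cut is still the
      # default optimal-modularity cut, so the warning is muffled.
      withCallingHandlers(
        memb(do.call(igraph::cluster_edge_betweenness, c(list(g), extra))),
        warning = function(w) {
          if (grepl("edge betweenness", conditionMessage(w), fixed = TRUE))
            invokeRestart("muffleWarning")
        })
    },
    LV = {
      if (!is.null(resolution)) params$resolution <- resolution
      function(g) memb(do.call(igraph::cluster_louvain,
                               c(list(g), params)))
    },
    LD = {
      if (!is.null(resolution)) params$resolution <- resolution
      function(g) memb(do.call(igraph::cluster_leiden,
                               c(list(g), params)))
    },
    LP = function(g) memb(do.call(igraph::cluster_label_prop,
                                  c(list(g), extra))),
    IM = function(g) memb(do.call(igraph::cluster_infomap,
                                  c(list(g), extra))),
    WT = {
      if (!is.null(steps)) params$steps <- steps
      function(g) memb(do.call(igraph::cluster_walktrap,
                               c(list(g), params)))
    },
    stop_input("unknown algorithm '", name,
               "'; available: eb, lv, ld, lp, im, wt")
  )
  meta <- list(
    EB = c(stochastic = FALSE, can_singleton = FALSE),
    LV = c(stochastic = TRUE,  can_singleton = FALSE),
    LD = c(stochastic = TRUE,  can_singleton = TRUE),
    LP = c(stochastic = TRUE,  can_singleton = FALSE),
    IM = c(stochastic = TRUE,  can_singleton = TRUE),
    WT = c(stochastic = FALSE, can_singleton = FALSE)
  )[[code]]
  community_adapter(fn, name = code, params = params,
                    stochastic = as.logical(meta["stochastic"]),
                    can_singleton = as.logical(meta["can_singleton"]))
}

as_adapter <- function(x) {
  if (inherits(x, "community_adapter")) return(x)
  if (is.character(x) && length(x) == 1L) return(builtin_adapter(x))
  if (is.function(x)) return(community_adapter(x, name = "user"))
  stop_input("`adapter` must be a community_adapter, an algorithm code, ",
             "or a function")
}
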