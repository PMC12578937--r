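#' Read a graph from a delimited edge-list file
#'
#' Each row is `source<delim>target` or `source<delim>target<delim>weight`.
#' Node order in the returned graph is first-appearance order in the file.
#' A header row is detected automatically when its fields match common column
#' names (source/target/from/to/weight) or, for weighted files, when the third
#' field is non-numeric; this can be forced with `header`.
#'
#' Duplicate undirected edges (`u,v` and `v,u` count as the same edge) are
#' collapsed into one edge whose weight is the sum of the duplicates, with a
#' warning.
#'
#' @param path Path to the file.
#' @param delimiter Field separator (default `","`).
#' @param weighted Is a third, positive numeric weight column present?
#' @param header One of `"auto"`, `"yes"`, `"no"`.
#' @return An undirected, named [igraph::igraph].
#' @export
read_edgelist <- function(path, delimiter = ",", weighted = FALSE,
                          header = c("auto", "yes", "no")) {
  header <- match.arg(header)
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_input("empty edge-list file: ", path)

  fields <- strsplit(lines, delimiter, fixed = TRUE)
  fields <- lapply(fields, trimws)
  want <- if (weighted) 3L else 2L

  header_names <- c("source", "target", "from", "to", "node1", "node2",
                    "weight", "w")
  is_header <- switch(header,
    yes = TRUE,
    no = FALSE,
    auto = {
      f1 <- tolower(fields[[1L]])
      name_match <- all(f1[1:2] %in% header_names)
      third_nonnum <- weighted && length(f1) >= 3L &&
        is.na(suppressWarnings(as.numeric(f1[3L])))
      name_match || third_nonnum
    })
  start <- if (is_header) 2L else 1L
  if (start > length(fields)) stop_input("edge-list file has a header but no data: ", path)

  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq(start, length(fields))) {
    f <- fields[[i]]
    if (length(f) != want)
      stop_input("malformed row at line ", i, ": expected ", want,
                 " fields, found ", length(f))
    wt <- if (weighted) suppressWarnings(as.numeric(f[3L])) else 1
    if (is.na(wt)) stop_input("non-numeric weight at line ", i)
    if (wt <= 0) stop_input("non-positive weight at line ", i)
    if (f[1L] == f[2L]) stop_input("self-loop at line ", i)
    from <- c(from, f[1L]); to <- c(to, f[2L]); w <- c(w, wt)
  }

  # first-appearance node order
  nodes <- unique(as.vector(rbind(from, to)))

  key <- ifelse(from < to, paste(from, to, sep = "\r"), paste(to, from, sep = "\r"))
  if (anyDuplicated(key)) {
    warning("duplicate undirected edges collapsed; weights summed",
            call. = FALSE)
    first <- !duplicated(key)
    wsum <- tapply(w, key, sum)
    from <- from[first]; to <- to[first]
    w <- as.numeric(wsum[key[first]])
  }
  edges <- data.frame(from = from, to = to, weight = w,
                      stringsAsFactors = FALSE)
  check_graph(graph_from_edges(edges, nodes))
}

#' Write a graph as a delimited edge list
#'
#' Writes a `source,target,weight` header followed by one row per edge, in the
#' graph's edge order. Isolated nodes cannot be represented in an edge list;
#' writing a graph that has any raises an error (use GraphML instead).
#'
#' @param g An undirected, named [igraph::igraph].
#' @param path Output path.
#' @param delimiter Field separator.
#' @export
write_edgelist <- function(g, path, delimiter = ",") {
  check_graph(g)
  if (any(igraph::degree(g) == 0))
    stop_input("edge lists cannot represent isolated nodes; use write_graphml()")
  edges <- igraph::as_data_frame(g, what = "edges")
  if (is.null(edges$weight)) edges$weight <- 1
  lines <- c(paste(c("source", "target", "weight"), collapse = delimiter),
             paste(edges$from, edges$to, format(edges$weight, trim = TRUE,
                                                scientific = FALSE),
                   sep = delimiter))
  writeLines(lines, path)
  invisible(path)
}

#' GraphML input and output
#'
#' Lossless interchange with the igraph/networkx ecosystems: node names, node
#' order, edges and weights round-trip exactly. Directed graphs are rejected.
#'
#' @param path File path.
#' @return `read_graphml()` returns an undirected, named [igraph::igraph].
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e) stop_input("cannot parse GraphML file ",
                                               path, ": ", conditionMessage(e)))
  if (igraph::is_directed(g)) stop_input("directed graphs are not supported")
  if (igraph::vcount(g) == 0L) stop_input("GraphML file has no nodes: ", path)
  if (is.null(igraph::V(g)$name)) {
    id <- igraph::vertex_attr(g, "id")
    igraph::V(g)$name <- id %||% as.character(seq_len(igraph::vcount(g)))
  }
  check_graph(g)
}

#' @rdname read_graphml
#' @param g An undirected, named [igraph::igraph].
#' @export
write_graphml <- function(g, path) {
  check_graph(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Partition input and output
#'
#' Partitions are written as two-column CSV (`node,community`) with community
#' labels recoded to canonical integers `0..k-1` in order of first node
#' appearance, and read back as named label vectors.
#'
#' @param p A partition: named vector mapping node name to community label.
#' @param path File path.
#' @export
write_partition <- function(p, path) {
  p <- as_partition(p)
  labs <- canonical_labels(p)
  utils::write.csv(data.frame(node = names(labs), community = unname(labs),
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c("character", "character"))
  if (!all(c("node", "community") %in% names(d)))
    stop_input("partition file must have columns node, community")
  as_partition(stats::setNames(d$community, d$node))
}
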