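#' Build a directed word multigraph from a token sequence
#'
#' Each distinct word becomes a node and each consecutive word pair a
#' directed edge from the earlier to the later word; identical consecutive
#' pairs accumulate multiplicity and an immediately repeated word yields a
#' self-loop. The total edge multiplicity of a graph built from `L` tokens is
#' therefore always `L - 1`.
#'
#' @param tokens non-empty character vector of word tokens.
#' @return an object of class `"word_graph"` with elements `nodes` (distinct
#'   words, in order of first appearance), `edges` (data.frame `source`,
#'   `target`, `count`), `token_length`, and `ids` (the token sequence coded
#'   as node indices).
#' @examples
#' g <- word_graph(c("the", "dog", "saw", "the", "cat"))
#' graph_attributes(g)
#' @export
word_graph <- function(tokens) {
  if (length(tokens) == 0) stop("cannot build a graph from an empty token sequence")
  tokens <- as.character(tokens)
  nodes <- unique(tokens)
  ids <- match(tokens, nodes)
  if (length(ids) > 1) {
    key <- paste(ids[-length(ids)], ids[-1], sep = ">")
    tab <- table(key)
    uv <- do.call(rbind, strsplit(names(tab), ">", fixed = TRUE))
    edges <- data.frame(source = nodes[as.integer(uv[, 1])],
                        target = nodes[as.integer(uv[, 2])],
                        count = as.integer(tab), stringsAsFactors = FALSE)
    edges <- edges[order(match(edges$source, nodes),
                         match(edges$target, nodes)), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(), target = character(),
                        count = integer(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges,
                 token_length = length(tokens), ids = ids),
            class = "word_graph")
}

#' @export
print.word_graph <- function(x, ...) {
  cat("Word graph:", length(x$nodes), "nodes,", sum(x$edges$count),
      "edge instances (", nrow(x$edges), "distinct ),",
      x$token_length, "tokens\n")
  invisible(x)
}

as_ids <- function(graph) {
  if (inherits(graph, "word_graph")) return(graph$ids)
  if (is.character(graph)) return(word_graph(graph)$ids)
  stop("expected a word_graph or a character token vector")
}

#' Word-graph attributes
#'
#' The four structural attributes of a word graph:
#' * `attr_N()` — lexical diversity: the number of nodes (distinct words).
#' * `attr_RE()` — short-range recurrence: the sum of edge multiplicities
#'   over ordered node pairs linked more than once (pairs traversed a single
#'   time contribute nothing). `re_mode = "excess"` instead counts total edge
#'   instances minus distinct pairs.
#' * `attr_LSC()` — long-range recurrence: the node count of the largest
#'   strongly connected component; an isolated node is its own component, so
#'   the result is at least 1. Edge multiplicities are irrelevant.
#' * `attr_ASP()` — graph size: the mean directed shortest-path length (in
#'   edge steps) over ordered node pairs `u != v` for which a path exists;
#'   unreachable pairs are excluded from the mean, and a graph with no
#'   reachable pair has ASP 0 (with a warning). `asp_mode = "undirected"`
#'   measures paths on the underlying undirected graph instead.
#'
#' `graph_attributes()` bundles all four into a named numeric vector
#' `c(N, RE, LSC, ASP)` and also accepts a raw token vector.
#'
#' @param graph a `"word_graph"` or a character token vector.
#' @param re_mode `"sum"` (default) or `"excess"`.
#' @param asp_mode `"directed"` (default) or `"undirected"`.
#' @return an integer (`attr_N`, `attr_RE`, `attr_LSC`), a non-negative
#'   number (`attr_ASP`), or a named numeric vector (`graph_attributes`).
#' @examples
#' graph_attributes(c("a", "b", "a", "b"))
#' @export
graph_attributes <- function(graph, re_mode = c("sum", "excess"),
                             asp_mode = c("directed", "undirected")) {
  re_mode <- match.arg(re_mode)
  asp_mode <- match.arg(asp_mode)
  a <- graph_attrs_cpp(as_ids(graph), asp_directed = asp_mode == "directed",
                       re_excess = re_mode == "excess")
  if (a[["finite_pairs"]] == 0 && a[["N"]] > 1)
    warning("no reachable ordered node pair; ASP defined as 0")
  c(N = a[["N"]], RE = a[["RE"]], LSC = a[["LSC"]], ASP = a[["ASP"]])
}

#' @rdname graph_attributes
#' @export
attr_N <- function(graph) length(if (inherits(graph, "word_graph"))
  graph$nodes else unique(as.character(graph)))

#' @rdname graph_attributes
#' @export
attr_RE <- function(graph, re_mode = c("sum", "excess")) {
  re_mode <- match.arg(re_mode)
  as.integer(graph_attrs_cpp(as_ids(graph),
                             re_excess = re_mode == "excess")[["RE"]])
}

#' @rdname graph_attributes
#' @export
attr_LSC <- function(graph)
  as.integer(graph_attrs_cpp(as_ids(graph))[["LSC"]])

#' @rdname graph_attributes
#' @export
attr_ASP <- function(graph, asp_mode = c("directed", "undirected")) {
  asp_mode <- match.arg(asp_mode)
  a <- graph_attrs_cpp(as_ids(graph),
                       asp_directed = asp_mode == "directed")
  if (a[["finite_pairs"]] == 0 && a[["N"]] > 1)
    warning("no reachable ordered node pair; ASP defined as 0")
  a[["ASP"]]
}

#' Convert a word graph to igraph / export it
#'
#' `as_igraph()` converts to an [igraph][igraph::graph_from_data_frame]
#' multigraph (one parallel edge per traversal); `write_word_graph()` writes
#' GraphML or DOT through igraph for visual inspection. Both require the
#' suggested igraph package.
#'
#' @param graph a `"word_graph"`.
#' @param path output file path.
#' @param format `"graphml"` or `"dot"`.
#' @export
as_igraph <- function(graph) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for conversion/export")
  stopifnot(inherits(graph, "word_graph"))
  e <- graph$edges
  el <- e[rep(seq_len(nrow(e)), e$count), c("source", "target"), drop = FALSE]
  igraph::graph_from_data_frame(el, directed = TRUE,
                                vertices = data.frame(name = graph$nodes))
}

#' @rdname as_igraph
#' @export
write_word_graph <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(graph), path, format = format)
  invisible(path)
}
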