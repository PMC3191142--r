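#' Per-subject directed causal graph
#'
#' Binary directed graph over labelled DMN nodes with a designated hub
#' subset; an edge (source, target) records a significant directed Granger
#' influence.  Self-loops are disallowed.
#'
#' @param node_labels Character vector of node names.
#' @param edges Data frame (or matrix) with columns `source` and `target`,
#'   or NULL/empty for an edgeless graph.
#' @param hub_labels Subset of `node_labels` treated as hubs (default
#'   [dmn_hub_labels()] intersected with `node_labels`).
#' @return An object of class `causal_graph`.
#' @export
causal_graph <- function(node_labels, edges = NULL,
                         hub_labels = intersect(dmn_hub_labels(),
                                                node_labels)) {
  node_labels <- as.character(node_labels)
  if (anyDuplicated(node_labels)) stop("node labels must be unique")
  if (!all(hub_labels %in% node_labels))
    stop("hub_labels must be a subset of node_labels")
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(source = character(0), target = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges <- data.frame(source = as.character(edges$source),
                        target = as.character(edges$target),
                        stringsAsFactors = FALSE)
    if (!all(edges$source %in% node_labels) ||
        !all(edges$target %in% node_labels))
      stop("edge endpoints must appear in node_labels")
    if (any(edges$source == edges$target))
      stop("self-loops are not allowed")
    if (anyDuplicated(paste(edges$source, edges$target, sep = "\r")))
      stop("duplicate edges")
  }
  structure(list(node_labels = node_labels,
                 hub_labels = as.character(hub_labels), edges = edges),
            class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("causal_graph: %d nodes (%d hubs), %d directed edges\n",
              length(x$node_labels), length(x$hub_labels), nrow(x$edges)))
  invisible(x)
}

#' Build the causal graph from a pairwise significance table
#'
#' The edge (s, t) is present iff the surrogate test of the directed
#' influence s to t was significant.
#'
#' @param edge_table Data frame as returned by [test_all_pairs()], with
#'   columns `source`, `target`, `significant`.
#' @param node_labels Node set of the graph (default: the labels appearing
#'   in the table).
#' @param hub_labels Hub subset.
#' @return A [causal_graph()].
#' @export
build_graph <- function(edge_table,
                        node_labels = sort(unique(c(edge_table$source,
                                                    edge_table$target))),
                        hub_labels = intersect(dmn_hub_labels(),
                                               node_labels)) {
  need <- c("source", "target", "significant")
  if (!all(need %in% names(edge_table)))
    stop("edge_table needs columns: ", paste(need, collapse = ", "))
  key <- paste(edge_table$source, edge_table$target, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (source, target) rows")
  sig <- edge_table[edge_table$significant %in% TRUE, c("source", "target")]
  causal_graph(node_labels, sig, hub_labels)
}

#' Hub-communication index of a causal graph
#'
#' Per-node out- and in-degrees plus the summary counts behind the hub
#' index: `d_all` is the total number of significant directed connections,
#' `d_outer` the number of those linking a hub with a non-hub (in either
#' direction), and `ratio = d_outer / d_all` measures how much of the
#' network's causal traffic runs between hubs and the periphery.  An
#' edgeless graph has an undefined ratio (flagged, returned as `NA`), not a
#' ratio of zero.
#'
#' @param graph A [causal_graph()].
#' @return An object of class `hub_index_result` with fields `d_out`,
#'   `d_in` (named per-node counts), `d_outer`, `d_all`, `ratio` and
#'   `ratio_defined`.
#' @examples
#' g <- causal_graph(c("PCC", "MPFC", "lITC"),
#'                   data.frame(source = "PCC", target = "lITC"),
#'                   hub_labels = c("PCC", "MPFC"))
#' hub_index(g)$ratio  # 1: the single edge is hub-to-non-hub
#' @export
hub_index <- function(graph) {
  stopifnot(inherits(graph, "causal_graph"))
  nodes <- graph$node_labels
  d_out <- table(factor(graph$edges$source, levels = nodes))
  d_in <- table(factor(graph$edges$target, levels = nodes))
  is_hub_s <- graph$edges$source %in% graph$hub_labels
  is_hub_t <- graph$edges$target %in% graph$hub_labels
  d_all <- nrow(graph$edges)
  d_outer <- sum(xor(is_hub_s, is_hub_t))
  structure(list(
    d_out = stats::setNames(as.integer(d_out), nodes),
    d_in = stats::setNames(as.integer(d_in), nodes),
    d_outer = as.integer(d_outer),
    d_all = as.integer(d_all),
    ratio = if (d_all > 0) d_outer / d_all else NA_real_,
    ratio_defined = d_all > 0), class = "hub_index_result")
}

#' @export
print.hub_index_result <- function(x, ...) {
  cat(sprintf("hub index: D_outer = %d, D_all = %d, D_outer/D_all = %s\n",
              x$d_outer, x$d_all,
              if (x$ratio_defined) sprintf("%.4f", x$ratio) else "undefined"))
  invisible(x)
}

#' Proportion of subjects carrying each directed edge
#'
#' Group-level summary underlying the edge-band graph figures: for every
#' ordered node pair, the fraction of subjects whose graph contains the
#' edge.
#'
#' @param graphs List of [causal_graph()]s sharing one node set.
#' @return Data frame with columns `source`, `target`, `proportion` (one
#'   row per ordered pair).
#' @export
group_edge_proportions <- function(graphs) {
  if (length(graphs) == 0) stop("need at least one graph")
  nodes <- graphs[[1]]$node_labels
  for (g in graphs) {
    stopifnot(inherits(g, "causal_graph"))
    if (!identical(g$node_labels, nodes))
      stop("all graphs must share the same node labels")
  }
  pairs <- expand.grid(target = nodes, source = nodes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, c("source", "target")]
  rownames(pairs) <- NULL
  key <- paste(pairs$source, pairs$target, sep = "\r")
  counts <- numeric(length(key))
  for (g in graphs) {
    gk <- paste(g$edges$source, g$edges$target, sep = "\r")
    counts <- counts + (key %in% gk)
  }
  pairs$proportion <- counts / length(graphs)
  pairs
}

#' Band an edge proportion as in the group connectivity figures
#'
#' Maps the fraction of subjects showing an edge onto the drawing bands:
#' `above_80` (> 0.8), `60_to_80` (\[0.6, 0.8\]), `50_to_60`
#' (\[0.5, 0.6)), and `below_50` (not drawn).
#'
#' @param fraction Numeric vector of proportions in \[0, 1\].
#' @return Factor with levels `below_50`, `50_to_60`, `60_to_80`,
#'   `above_80`.
#' @export
categorize_proportion <- function(fraction) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]")
  lev <- c("below_50", "50_to_60", "60_to_80", "above_80")
  out <- ifelse(fraction > 0.8, "above_80",
         ifelse(fraction >= 0.6, "60_to_80",
         ifelse(fraction >= 0.5, "50_to_60", "below_50")))
  factor(out, levels = lev)
}
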