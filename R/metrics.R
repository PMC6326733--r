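# Nodal and global graph statistics.

graph_edge_list <- function(graph) {
  adj <- graph$adjacency
  idx <- which(adj != 0 & upper.tri(adj), arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  dimnames(idx) <- NULL
  idx
}

require_binary <- function(graph, fn) {
  stopifnot(inherits(graph, "thresholded_graph"))
  if (graph$weighted) {
    abort(sprintf("%s() requires a binary graph", fn), class = "whackanode_type_error")
  }
  invisible(graph)
}

#' Degree centrality
#'
#' @param graph A binary `thresholded_graph`.
#' @return A tibble with columns `node` and `degree`.
#' @export
node_degree <- function(graph) {
  require_binary(graph, "node_degree")
  tibble(node = seq_len(graph$n_nodes), degree = as.numeric(colSums(graph$adjacency)))
}

#' Strength centrality
#'
#' Sum of policy-applied incident edge weights. A binary graph is accepted and
#' reduces to degree.
#'
#' @param graph A `thresholded_graph` (weighted or binary).
#' @return A tibble with columns `node` and `strength`.
#' @export
node_strength <- function(graph) {
  stopifnot(inherits(graph, "thresholded_graph"))
  tibble(node = seq_len(graph$n_nodes), strength = as.numeric(colSums(graph$adjacency)))
}

#' Within- or between-module degree
#'
#' Counts a node's incident edges to neighbors of its own module (`within`) or
#' of other modules (`between`); the two always sum to degree.
#'
#' @param graph A binary `thresholded_graph`.
#' @param partition A `module_partition` covering all nodes.
#' @param scope `"within"` or `"between"`.
#' @return A tibble with columns `node`, `module`, `degree`.
#' @export
module_degree <- function(graph, partition, scope = c("within", "between")) {
  scope <- match.arg(scope)
  require_binary(graph, "module_degree")
  partition <- as_partition(partition)
  if (nrow(partition) != graph$n_nodes) {
    stop_validation("partition does not cover the graph's nodes")
  }
  mod <- module_ids(partition)
  edges <- graph_edge_list(graph)
  same <- mod[edges[, 1]] == mod[edges[, 2]]
  pick <- if (scope == "within") same else !same
  ends <- c(edges[pick, 1], edges[pick, 2])
  tibble(
    node = seq_len(graph$n_nodes),
    module = partition$module,
    degree = as.numeric(tabulate(ends, graph$n_nodes))
  )
}

#' Z-score metric values within strata
#'
#' Standardizes a tidy metric table within each stratum (by default module x
#' density/cutoff): subtract the stratum mean and divide by the stratum SD
#' (denominator n - 1). Zero-variance strata yield `NA` z values, are flagged
#' in the `zero_variance` column, and trigger a warning rather than being
#' dropped.
#'
#' @param data A data frame of metric values.
#' @param value Name of the value column to standardize.
#' @param strata Character vector of stratum columns present in `data`.
#' @return `data` with added columns `z` and `zero_variance`, as a tibble.
#' @export
zscore_by_module_density <- function(data, value = "degree",
                                     strata = c("module", "cutoff")) {
  missing_cols <- setdiff(c(value, strata), names(data))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  out <- data %>%
    as_tibble() %>%
    group_by(across(all_of(strata))) %>%
    mutate(
      .n = dplyr::n(),
      .sd = sd(.data[[value]]),
      zero_variance = .data$.n < 2 | .data$.sd == 0 | !is.finite(.data$.sd),
      z = ifelse(.data$zero_variance, NA_real_,
                 (.data[[value]] - mean(.data[[value]])) / .data$.sd)
    ) %>%
    ungroup() %>%
    select(-".n", -".sd")
  if (any(out$zero_variance)) {
    warn(sprintf(
      "%d observation(s) fall in zero-variance strata; their z is NA",
      sum(out$zero_variance)
    ))
  }
  out
}

#' Global transitivity
#'
#' Ratio of 3 x triangles to connected triples (the global clustering
#' statistic, not the mean local clustering coefficient). Graphs with no
#' connected triples return 0 with a warning.
#'
#' @param graph A binary `thresholded_graph`.
#' @return A single number in \[0, 1\].
#' @export
graph_transitivity <- function(graph) {
  require_binary(graph, "graph_transitivity")
  ct <- cpp_transitivity(graph_edge_list(graph), graph$n_nodes)
  if (is.nan(ct)) {
    warn("graph has no connected triples; transitivity defined as 0")
    return(0)
  }
  ct
}

#' Characteristic path length
#'
#' Mean shortest-path length over reachable ordered node pairs. Disconnected
#' pairs are excluded from the mean and their count reported.
#'
#' @param graph A binary `thresholded_graph`.
#' @return A one-row tibble with `path_length`, `n_reachable_pairs`, and
#'   `n_unreachable_pairs` (ordered pairs, self-pairs excluded).
#' @export
char_path_length <- function(graph) {
  require_binary(graph, "char_path_length")
  res <- cpp_path_length(graph_edge_list(graph), graph$n_nodes)
  if (res[2] == 0) {
    abort("graph has no edges: path length undefined",
          class = "whackanode_degenerate_graph")
  }
  tibble(
    path_length = res[1] / res[2],
    n_reachable_pairs = res[2],
    n_unreachable_pairs = res[3]
  )
}
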