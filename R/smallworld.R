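# Small-worldness against degree-preserving rewired null ensembles.

#' Attempted-swap budget for degree-preserving rewiring
#'
#' The null-model randomizer performs `swaps_per_edge` double-edge-swap
#' attempts per edge slot. The default `"edges"` budget scales with the actual
#' edge count `E`; the `"pairs"` budget counts every unique node pair
#' `N(N-1)/2` as a slot, the convention under which a 264-node graph at 10
#' swaps per slot yields 347,160 attempts.
#'
#' @param n_edges Edge count (required for `budget = "edges"`).
#' @param n_nodes Node count (required for `budget = "pairs"`).
#' @param swaps_per_edge Attempts per slot.
#' @param budget `"edges"` or `"pairs"`.
#' @return The attempted-swap count.
#' @examples
#' swap_budget(n_nodes = 264, budget = "pairs")
#' @export
swap_budget <- function(n_edges = NULL, n_nodes = NULL, swaps_per_edge = 10,
                        budget = c("edges", "pairs")) {
  budget <- match.arg(budget)
  if (budget == "edges") {
    if (is.null(n_edges)) stop_config("budget = 'edges' needs n_edges")
    swaps_per_edge * n_edges
  } else {
    if (is.null(n_nodes)) stop_config("budget = 'pairs' needs n_nodes")
    swaps_per_edge * n_nodes * (n_nodes - 1) / 2
  }
}

#' Degree-preserving rewiring (double edge swaps)
#'
#' Randomizes a binary graph by repeatedly exchanging the endpoints of two
#' edges, rejecting swaps that would create self-loops or multi-edges, so the
#' degree sequence is preserved exactly.
#'
#' @param graph A binary `thresholded_graph` with at least two edges.
#' @param swaps_per_edge Attempted swaps per budget slot.
#' @param budget See [swap_budget()].
#' @param seed Optional substream seed; `NULL` uses the ambient RNG state.
#' @return A rewired `thresholded_graph` with attributes `achieved_swaps` and
#'   `attempted_swaps`.
#' @export
rewire_preserving_degree <- function(graph, swaps_per_edge = 10,
                                     budget = c("edges", "pairs"), seed = NULL) {
  budget <- match.arg(budget)
  require_binary(graph, "rewire_preserving_degree")
  set_substream(seed, 41L)
  edges <- graph_edge_list(graph)
  attempts <- swap_budget(n_edges = nrow(edges), n_nodes = graph$n_nodes,
                          swaps_per_edge = swaps_per_edge, budget = budget)
  res <- cpp_rewire_degseq(edges, graph$n_nodes, attempts)
  adj <- matrix(0, graph$n_nodes, graph$n_nodes)
  adj[res$edges] <- 1
  adj[res$edges[, c(2, 1), drop = FALSE]] <- 1
  out <- new_thresholded_graph(adj, graph$spec$strategy, graph$spec$cutoff,
                               graph$spec$negative_policy, weighted = FALSE)
  attr(out, "achieved_swaps") <- res$achieved_swaps
  attr(out, "attempted_swaps") <- res$attempted_swaps
  out
}

# sigma ingredients from an edge list: transitivity and path length of the
# largest connected component (single compiled pass); a null graph that
# happens to disconnect is evaluated on its own largest component
lcc_stats <- function(edges, n) {
  s <- cpp_lcc_stats(edges, n)
  list(
    transitivity = if (is.nan(s[1])) 0 else s[1],
    path_length = s[2] / s[3]
  )
}

#' Small-worldness coefficient
#'
#' Humphries-Gurney sigma: `(C_g / C_rand) / (L_g / L_rand)`, where `C` is
#' global transitivity and `L` characteristic path length, and the `rand`
#' terms are means over an ensemble of degree-preserving rewired null graphs.
#' Values well above 1 indicate small-world topology. Disconnected input is
#' reduced to its largest connected component, with the coverage reported.
#'
#' @param graph A binary `thresholded_graph`.
#' @param n_null Null-ensemble size.
#' @param swaps_per_edge,budget Rewiring effort; see [swap_budget()].
#' @param seed Optional substream seed for the null ensemble.
#' @return A one-row tibble: `sigma`, `c_g`, `l_g`, `c_rand`, `l_rand`,
#'   `n_null`, `component_coverage`.
#' @export
small_worldness <- function(graph, n_null = 100, swaps_per_edge = 10,
                            budget = c("edges", "pairs"), seed = NULL) {
  budget <- match.arg(budget)
  require_binary(graph, "small_worldness")
  if (n_null < 1) stop_config("n_null must be >= 1")
  set_substream(seed, 43L)
  sigma_from_edges(graph_edge_list(graph), graph$n_nodes, n_null,
                   swaps_per_edge, budget)
}

# sigma machinery on a raw edge list; RNG state is the caller's
sigma_from_edges <- function(edges, n_nodes, n_null, swaps_per_edge, budget) {
  # reduce to the target's largest component once; nulls rewire its edges
  comp <- cpp_components(edges, n_nodes)
  sizes <- tabulate(comp)
  main <- which.max(sizes)
  coverage <- sizes[main] / n_nodes
  n <- n_nodes
  if (coverage < 1) {
    keep_nodes <- which(comp == main)
    relabel <- integer(n_nodes)
    relabel[keep_nodes] <- seq_along(keep_nodes)
    pick <- comp[edges[, 1]] == main
    edges <- cbind(relabel[edges[pick, 1]], relabel[edges[pick, 2]])
    n <- length(keep_nodes)
  }
  target <- lcc_stats(edges, n)
  attempts <- swap_budget(n_edges = nrow(edges), n_nodes = n,
                          swaps_per_edge = swaps_per_edge, budget = budget)
  c_rand <- numeric(n_null)
  l_rand <- numeric(n_null)
  for (k in seq_len(n_null)) {
    res <- cpp_rewire_degseq(edges, n, attempts)
    ing <- lcc_stats(res$edges, n)
    c_rand[k] <- ing$transitivity
    l_rand[k] <- ing$path_length
  }
  c_rand_mean <- mean(c_rand)
  l_rand_mean <- mean(l_rand)
  if (c_rand_mean == 0) {
    abort(sprintf(
      paste0("sigma undefined: null transitivity is 0 ",
             "(C_g = %.4f, L_g = %.4f, L_rand = %.4f)"),
      target$transitivity, target$path_length, l_rand_mean
    ), class = "whackanode_sigma_undefined")
  }
  tibble(
    sigma = (target$transitivity / c_rand_mean) / (target$path_length / l_rand_mean),
    c_g = target$transitivity, l_g = target$path_length,
    c_rand = c_rand_mean, l_rand = l_rand_mean,
    n_null = n_null, component_coverage = coverage
  )
}
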