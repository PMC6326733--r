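# Edge-definition strategies. All three accept a subject_matrix, ground_truth,
# or plain symmetric matrix; the diagonal is always ignored.

apply_negative_policy <- function(values, negative_policy) {
  switch(negative_policy,
    discard = pmax(values, 0),
    abs = abs(values),
    retain = values,
    stop_config(sprintf("unknown negative_policy '%s'", negative_policy))
  )
}

new_thresholded_graph <- function(adjacency, strategy, cutoff, negative_policy,
                                  weighted) {
  n <- nrow(adjacency)
  e <- sum(adjacency[upper.tri(adjacency)] != 0)
  structure(
    list(
      adjacency = adjacency,
      spec = list(strategy = strategy, cutoff = cutoff,
                  negative_policy = negative_policy),
      n_nodes = n, n_edges = e,
      density = 2 * e / (n * (n - 1)),
      mean_degree = 2 * e / n,
      weighted = weighted
    ),
    class = "thresholded_graph"
  )
}

#' Binarize a matrix by proportional (density) thresholding
#'
#' Ranks the `N(N-1)/2` unique off-diagonal values by signed value after
#' applying the negative-edge policy and retains the top
#' `round(density * N(N-1)/2)` as edges (round-half-even). Ties at the cutoff
#' are broken by node-pair lexicographic order, so the edge count is exact and
#' identical across subjects -- the property that equates density and mean
#' degree between groups.
#'
#' @param matrix A `subject_matrix`, `ground_truth`, or symmetric matrix.
#' @param density Target edge density in (0, 1].
#' @param negative_policy `"discard"` (default; negative edges can never be
#'   retained), `"abs"`, or `"retain"`.
#' @return A binary `thresholded_graph`.
#' @export
binarize_proportional <- function(matrix, density, negative_policy = "discard") {
  if (density <= 0 || density > 1) stop_config("density must be in (0, 1]")
  w <- as_fc_matrix(matrix)
  n <- nrow(w)
  values <- apply_negative_policy(ut_values(w), negative_policy)
  m_target <- round(density * length(values))
  if (m_target == 0) {
    stop_degenerate(sprintf("density %.4f retains 0 of %d edges", density, length(values)))
  }
  eligible <- if (negative_policy == "discard") values > 0 else rep.int(TRUE, length(values))
  if (m_target > sum(eligible)) {
    warn(sprintf(
      "only %d eligible edges for a target of %d; retaining all eligible edges",
      sum(eligible), m_target
    ))
    m_target <- sum(eligible)
  }
  pairs <- upper_pairs(n)
  ord <- order(-values, pairs[, "i"], pairs[, "j"])
  ord <- ord[eligible[ord]]
  keep <- ord[seq_len(m_target)]
  adj <- matrix(0, n, n)
  adj[pairs[keep, , drop = FALSE]] <- 1
  adj <- adj + t(adj)
  new_thresholded_graph(adj, "proportional", density, negative_policy, weighted = FALSE)
}

#' Binarize a matrix at an absolute FC cutoff
#'
#' An edge is present iff its (policy-applied) value exceeds `r_cutoff`.
#' Density and mean degree are free to differ between subjects.
#'
#' @inheritParams binarize_proportional
#' @param r_cutoff Correlation cutoff, |r_cutoff| < 1.
#' @param on_empty `"error"` (default) raises a degenerate-graph error when no
#'   edge survives; `"empty"` returns the empty graph instead, which the
#'   experiment drivers use so that a single extreme subject cannot abort a
#'   replication.
#' @return A binary `thresholded_graph`.
#' @export
binarize_absolute <- function(matrix, r_cutoff, negative_policy = "discard",
                              on_empty = c("error", "empty")) {
  on_empty <- match.arg(on_empty)
  if (abs(r_cutoff) >= 1) stop_config("|r_cutoff| must be < 1")
  w <- as_fc_matrix(matrix)
  n <- nrow(w)
  values <- apply_negative_policy(ut_values(w), negative_policy)
  keep <- which(values > r_cutoff)
  if (length(keep) == 0 && on_empty == "error") {
    stop_degenerate(sprintf(
      "no edges exceed r = %.3f (max observed value %.4f)", r_cutoff, max(values)
    ))
  }
  pairs <- upper_pairs(n)
  adj <- matrix(0, n, n)
  if (length(keep) > 0) adj[pairs[keep, , drop = FALSE]] <- 1
  adj <- adj + t(adj)
  new_thresholded_graph(adj, "absolute", r_cutoff, negative_policy, weighted = FALSE)
}

#' Convert a matrix to a weighted graph under a negative-edge policy
#'
#' @inheritParams binarize_proportional
#' @param negative_policy `"discard"` zeroes negative weights, `"abs"`
#'   rectifies them, `"retain"` passes them through.
#' @return A weighted `thresholded_graph`.
#' @export
to_weighted <- function(matrix, negative_policy = c("discard", "abs", "retain")) {
  negative_policy <- match.arg(negative_policy)
  w <- as_fc_matrix(matrix)
  adj <- apply_negative_policy(w, negative_policy)
  diag(adj) <- 0
  new_thresholded_graph(adj, "weighted", NA_real_, negative_policy, weighted = TRUE)
}

#' Edge count, density, and mean degree of a binary graph
#'
#' Reports `E`, `D = 2E / (N(N-1))`, and `<k> = 2E / N`; the identity
#' `<k> = D (N - 1)` holds to machine precision.
#'
#' @param graph A binary `thresholded_graph`.
#' @return A one-row tibble with columns `n_edges`, `density`, `mean_degree`.
#' @export
density_mean_degree <- function(graph) {
  stopifnot(inherits(graph, "thresholded_graph"))
  if (graph$weighted) {
    abort("density_mean_degree() is defined for binary graphs only",
          class = "whackanode_type_error")
  }
  tibble(n_edges = graph$n_edges, density = graph$density,
         mean_degree = graph$mean_degree)
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf(
    "<thresholded_graph> %s (cutoff %s, negatives: %s): N = %d, E = %d, D = %.4f\n",
    x$spec$strategy, format(x$spec$cutoff), x$spec$negative_policy,
    x$n_nodes, x$n_edges, x$density
  ))
  invisible(x)
}

#' Nodal degree across a grid of thresholds
#'
#' Vectorized driver used throughout the experiments: one ranking of the
#' upper-triangle values serves every cutoff in the grid. Equivalent to
#' calling [binarize_proportional()] / [binarize_absolute()] per cutoff and
#' taking [node_degree()], but much faster.
#'
#' @param matrix A `subject_matrix`, `ground_truth`, or symmetric matrix.
#' @param strategy `"proportional"` (cutoffs are densities) or `"absolute"`
#'   (cutoffs are correlation values).
#' @param cutoffs Numeric vector of cutoffs.
#' @param negative_policy See [binarize_proportional()].
#' @return A tibble with columns `node`, `cutoff`, `degree`, and
#'   `graph_density` (realized density of the thresholded graph).
#' @export
degree_by_threshold <- function(matrix, strategy = c("proportional", "absolute"),
                                cutoffs, negative_policy = "discard") {
  strategy <- match.arg(strategy)
  w <- as_fc_matrix(matrix)
  n <- nrow(w)
  values <- apply_negative_policy(ut_values(w), negative_policy)
  pairs <- upper_pairs(n)
  counts <- threshold_degree_counts(values, pairs, n, strategy, cutoffs, negative_policy)
  tibble(
    node = rep.int(seq_len(n), length(cutoffs)),
    cutoff = rep(cutoffs, each = n),
    degree = as.vector(counts$degrees),
    graph_density = rep(counts$densities, each = n)
  )
}

# core shared by degree_by_threshold() and the experiment drivers: takes
# policy-applied upper-tri values, returns degrees (node x cutoff) + densities
threshold_degree_counts <- function(values, pairs, n, strategy, cutoffs,
                                    negative_policy) {
  m_all <- length(values)
  ord <- order(-values, pairs[, "i"], pairs[, "j"])
  if (negative_policy == "discard") {
    n_eligible <- sum(values > 0)
  } else {
    n_eligible <- m_all
  }
  sorted_desc <- values[ord]
  degrees <- matrix(0L, n, length(cutoffs))
  densities <- numeric(length(cutoffs))
  for (c_idx in seq_along(cutoffs)) {
    if (strategy == "proportional") {
      m_keep <- round(cutoffs[c_idx] * m_all)
      if (m_keep > n_eligible) m_keep <- n_eligible
    } else {
      m_keep <- sum(sorted_desc > cutoffs[c_idx])
      if (negative_policy == "discard") m_keep <- min(m_keep, n_eligible)
    }
    if (m_keep > 0) {
      keep <- ord[seq_len(m_keep)]
      degrees[, c_idx] <- tabulate(pairs[keep, "i"], n) + tabulate(pairs[keep, "j"], n)
    }
    densities[c_idx] <- m_keep / m_all
  }
  list(degrees = degrees, densities = densities)
}
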