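# small fixtures built in code; kept deliberately tiny so unit tests are fast

small_gt <- function(seed = 1, n = 40, k = 4) {
  generate_groundtruth(generate_partition(n, n_modules = k), seed = seed)
}

# a partition that carries the focal module labels at reduced size
focal_partition <- function() {
  generate_partition(
    60,
    module_sizes = c(14, 10, 4, 12, 8, 12),
    module_names = c("DMN", "FPN", "DAN", "Visual", "Somatomotor", "Other")
  )
}

# wrap a plain adjacency matrix as a thresholded_graph
as_graph <- function(adj, weighted = FALSE) {
  adj <- as.matrix(adj)
  diag(adj) <- 0
  whackanode:::new_thresholded_graph(adj, "absolute", 0, "retain", weighted = weighted)
}

# adjacency from an edge list on n nodes
adj_from_edges <- function(edges, n) {
  a <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    a[edges[r, 1], edges[r, 2]] <- 1
    a[edges[r, 2], edges[r, 1]] <- 1
  }
  a
}

random_graph <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# --- brute-force graph oracles (independent of the package implementation) ---

oracle_degree <- function(adj) rowSums(adj != 0)

oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) return(NaN)
  triangles <- 0
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        for (k in (j + 1):n) {
          if (adj[i, j] && adj[j, k] && adj[i, k]) triangles <- triangles + 1
        }
      }
    }
  }
  3 * triangles / triples
}

oracle_path_length <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  off <- d[row(d) != col(d)]
  list(
    path_length = mean(off[is.finite(off)]),
    n_unreachable = sum(!is.finite(off))
  )
}

# all simple graphs on n nodes (n small), as adjacency matrices
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- bits
    a + t(a)
  })
}
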