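# shared internal helpers

# indices of the unique node pairs (i < j) of an N-node graph, column-bound
upper_pairs <- function(n) {
  # column-major over the upper triangle: for j in 2..n, i in 1..(j-1)
  j <- rep.int(2:n, 1:(n - 1))
  i <- sequence(1:(n - 1))
  cbind(i = i, j = j)
}

# upper-triangle values of a symmetric matrix in upper_pairs() order
ut_values <- function(mat) {
  mat[upper.tri(mat)][ut_order_fix(nrow(mat))]
}

# upper.tri() extracts column-major (i<j sorted by j then i), which is exactly
# upper_pairs() order; identity kept explicit so a future reordering is caught
ut_order_fix <- function(n) seq_len(n * (n - 1L) / 2L)

# rebuild a symmetric matrix (unit diagonal by default) from upper-tri values
ut_to_matrix <- function(values, n, diag_value = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- values
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(msg) abort(msg, class = "whackanode_config_error")
stop_design <- function(msg) abort(msg, class = "whackanode_design_error")
stop_validation <- function(msg) abort(msg, class = "whackanode_validation_error")
stop_degenerate <- function(msg) abort(msg, class = "whackanode_degenerate_graph")
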