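#' Derive a reproducible substream seed
#'
#' Collapses a master seed plus any number of integer indices (replication
#' number, subject number, stage id, ...) into a single seed in
#' `[1, 2^31 - 2]` by iterated integer hashing. The same `(seed, indices)`
#' tuple always yields the same substream, so any replication of an experiment
#' can be re-created in isolation without replaying the ones before it.
#'
#' @param seed Master integer seed.
#' @param ... Further non-negative integer indices identifying the substream.
#' @return A single integer seed.
#' @examples
#' substream_seed(42, 3, 1)
#' @export
substream_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  stopifnot(is.numeric(idx), all(is.finite(idx)))
  h <- 104729
  for (x in idx) {
    # constants keep intermediate products < 2^53 for exact double arithmetic
    h <- (h * 69069 + (abs(x) + 1) * 40503 + 12345) %% 2147483629
  }
  as.integer(h %% 2147483627 + 1)
}

# set the RNG for a substream unless the caller wants the ambient stream
set_substream <- function(seed, ...) {
  if (!is.null(seed)) set.seed(substream_seed(seed, ...))
  invisible(NULL)
}
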