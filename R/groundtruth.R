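#' Generate a synthetic groundtruth functional connectivity matrix
#'
#' Builds the fixed correlation matrix that every simulated subject perturbs.
#' Rather than sampling matrix entries directly, the generator mixes latent
#' time series -- one signal per module, one global signal, and per-node
#' noise -- and returns their pairwise Pearson correlation matrix, which is
#' therefore always a valid (positive semidefinite) correlation matrix. A
#' random hub subset additionally loads on several foreign module signals,
#' producing the heavy right tail of node strength seen in empirical
#' connectomes. Per-node loading jitter spreads the edge-weight distribution
#' the way heterogeneous regional coupling does in real data.
#'
#' Besides the global and module signals, every node carries a signed loading
#' on an "anticorrelation" factor, mimicking the broad positive-to-negative
#' dispersion of edge weights (including anticorrelated systems) seen in
#' single-subject FC matrices estimated without global signal regression.
#'
#' Defaults give a broadly dispersed edge-weight distribution (mean
#' off-diagonal correlation around 0.25-0.3, SD around 0.25, a right tail
#' reaching past r = .8) so that density thresholds of 5-25% and correlation
#' cutoffs of .2-.5 are all non-degenerate for every simulated subject and the
#' degree response to person-level FC offsets stays approximately linear
#' across that whole range. The default `n_timepoints = 60` approximates the
#' effective degrees of freedom of a band-passed (~0.01-0.08 Hz) five-minute
#' resting-state scan, whose sampling noise is a further source of edge-weight
#' dispersion.
#'
#' @param partition A `module_partition` (see [generate_partition()]).
#' @param n_timepoints Length of the latent time series (>= 50).
#' @param within_loading Loading of each node on its own module signal, in
#'   `[0, 1)`; squared, it is the share of node variance from the module
#'   signal.
#' @param between_loading Loading of each node on the global signal, in
#'   `[0, within_loading]`; `between_loading^2` sets the baseline
#'   between-module correlation.
#' @param signed_loading SD of the zero-mean normal loadings on the
#'   anticorrelation factor; 0 disables it.
#' @param hub_fraction Fraction of nodes promoted to hubs that also load on
#'   `n_hub_modules` foreign module signals.
#' @param n_hub_modules Number of foreign module signals each hub loads on.
#' @param loading_jitter Log-scale SD of the multiplicative jitter on each
#'   node's global coupling.
#' @param within_jitter Half-width of the uniform multiplicative jitter on
#'   each node's module loading.
#' @param density_exponent Rate at which within-module coupling decays with
#'   module size (larger communities are internally sparser, keeping baseline
#'   nodal degree roughly flat across modules); 0 disables the decay.
#' @param exchange_sets A list of two module-label vectors whose node sets are
#'   made exchangeable: the second set's nodal coupling draws (global, signed,
#'   and within-module jitter) are copied from the first, and connector hubs
#'   are placed outside both. This gives the case-control modular design two
#'   statistically identical substrates, so its group contrast is not
#'   confounded by sampling accidents of the synthetic connectome. Applied
#'   only when all labels are present and the two sets have equal size;
#'   `NULL` disables the matching.
#' @param seed Integer seed; the same seed always yields the same matrix.
#' @return An object of class `ground_truth`: a list with `values` (N x N
#'   correlation matrix), `partition`, and `params`.
#' @examples
#' gt <- generate_groundtruth(generate_partition(40, n_modules = 4), seed = 1)
#' fc_summary(gt)
#' @export
generate_groundtruth <- function(partition,
                                 n_timepoints = 60,
                                 within_loading = 0.78,
                                 between_loading = 0.28,
                                 signed_loading = 0.30,
                                 hub_fraction = 0.12,
                                 n_hub_modules = 4,
                                 loading_jitter = 0.6,
                                 within_jitter = 0.15,
                                 density_exponent = 0.22,
                                 exchange_sets = list(c("FPN", "DAN"), "DMN"),
                                 seed = 1) {
  partition <- as_partition(partition)
  if (n_timepoints < 50) stop_config("n_timepoints must be >= 50")
  if (between_loading < 0 || within_loading >= 1 || between_loading > within_loading) {
    stop_config("loadings must satisfy 0 <= between_loading <= within_loading < 1")
  }
  n <- nrow(partition)
  mod <- module_ids(partition)
  k <- nlevels(partition$module)

  matched <- NULL
  if (!is.null(exchange_sets) &&
      all(unlist(exchange_sets) %in% levels(partition$module))) {
    a <- module_nodes(partition, exchange_sets[[1]])
    b <- module_nodes(partition, exchange_sets[[2]])
    if (length(a) == length(b)) matched <- list(a = a, b = b)
  }

  # effective latent-community structure: the second matched set is split
  # into sub-blocks mirroring the first set's module sizes (e.g. the DMN
  # gets two subsystems sized like FPN and DAN), each with its own latent
  # signal. The partition label is untouched; only the generator's block
  # structure changes, making the two substrates exchangeable edge for edge.
  emod <- mod
  k_eff <- k
  if (!is.null(matched)) {
    run_sizes <- rle(mod[matched$a])$lengths
    start <- 0L
    for (sz in run_sizes) {
      k_eff <- k_eff + 1L
      emod[matched$b[(start + 1L):(start + sz)]] <- k_eff
      start <- start + sz
    }
  }

  set_substream(seed, 11L)

  # columns: global factor, anticorrelation factor, then one per module.
  # centred and orthogonalized so that factor-level sampling correlations
  # (order 1/sqrt(T)) cannot shift a whole module's baseline FC; edgewise
  # sampling dispersion still enters through the per-node noise below
  signals <- matrix(rnorm(n_timepoints * (k_eff + 2)), n_timepoints, k_eff + 2)
  signals <- scale(signals, center = TRUE, scale = FALSE)
  signal_q <- qr.Q(qr(signals))
  signals <- scale(signal_q)
  load <- matrix(0, n, k_eff + 2)
  # lognormal jitter (unit mean): regional global coupling is right-skewed,
  # which carries through to a right-skewed node-strength distribution
  global_jit <- stats::rlnorm(n, -loading_jitter^2 / 2, loading_jitter)
  signed_jit <- rnorm(n, 0, signed_loading)
  within_jit <- runif(n, 1 - within_jitter, 1 + within_jitter)
  if (!is.null(matched)) {
    global_jit[matched$b] <- global_jit[matched$a]
    signed_jit[matched$b] <- signed_jit[matched$a]
    within_jit[matched$b] <- within_jit[matched$a]
  }
  load[, 1] <- between_loading * global_jit
  load[, 2] <- signed_jit
  size_of <- tabulate(emod, k_eff)
  within_scale <- pmin((12 / size_of[emod])^density_exponent, 1.1)
  load[cbind(seq_len(n), emod + 2L)] <-
    within_loading * within_scale * within_jit

  n_hub <- ceiling(hub_fraction * n)
  hubs <- integer(0)
  hub_pool <- setdiff(seq_len(n), c(matched$a, matched$b))
  n_hub <- min(n_hub, length(hub_pool))
  # hubs live outside the matched sets and do not load on their modules,
  # so the matched substrates stay exchangeable
  blocked_modules <- unique(emod[c(matched$a, matched$b)])
  if (n_hub > 0 && k_eff > 1 && within_loading > 0) {
    hubs <- sample(hub_pool, n_hub)
    hub_loading <- 0.35 * within_loading
    for (h in hubs) {
      foreign <- setdiff(seq_len(k_eff), c(emod[h], blocked_modules))
      picked <- sample(foreign, min(n_hub_modules, length(foreign)))
      load[h, picked + 2L] <- hub_loading * runif(length(picked), 0.8, 1.2)
      # connector profile: broad global coupling, weaker module specificity
      load[h, 1] <- min(2.2 * load[h, 1], 0.7)
      load[h, emod[h] + 2L] <- 0.5 * load[h, emod[h] + 2L]
    }
  }

  noise_var <- pmax(1 - rowSums(load^2), 0.15)
  # per-node noise orthogonalized against the factor space; matched-set
  # nodes share their twins' noise vectors, which makes every internal and
  # spoke correlation of the two substrates identical by construction (the
  # 36 twin pairs themselves carry elevated FC, equally for both groups)
  noise <- matrix(rnorm(n_timepoints * n), n_timepoints, n)
  noise <- noise - signal_q %*% crossprod(signal_q, noise)
  noise <- scale(noise)
  if (!is.null(matched)) noise[, matched$b] <- noise[, matched$a]
  x <- signals %*% t(load) + noise * rep(sqrt(noise_var), each = n_timepoints)
  w <- cor(x)
  dimnames(w) <- list(partition$node, partition$node)
  diag(w) <- 1

  out <- structure(
    list(
      values = w,
      partition = partition,
      params = list(
        n_timepoints = n_timepoints, within_loading = within_loading,
        between_loading = between_loading, signed_loading = signed_loading,
        hub_fraction = hub_fraction,
        n_hub_modules = n_hub_modules, loading_jitter = loading_jitter,
        within_jitter = within_jitter, density_exponent = density_exponent,
        exchange_sets = exchange_sets, hubs = sort(hubs), seed = seed
      )
    ),
    class = "ground_truth"
  )
  # with all structure switched off the mean-FC and modular-contrast
  # invariants do not apply (the matrix is pure sampling noise)
  validate_groundtruth(out, structure = within_loading > 0 || between_loading > 0)
}

#' Construct a groundtruth object from an existing matrix
#'
#' @param values A symmetric correlation matrix with unit diagonal.
#' @param partition A `module_partition` covering the matrix nodes.
#' @param tol_asymmetry Maximum absolute asymmetry tolerated before erroring;
#'   below it the matrix is symmetrized by averaging with its transpose.
#' @return A validated `ground_truth` object.
#' @export
as_groundtruth <- function(values, partition, tol_asymmetry = 1e-8) {
  partition <- as_partition(partition)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop_validation(sprintf(
      "matrix must be square, got %d rows x %d columns", nrow(values), ncol(values)
    ))
  }
  if (nrow(values) != nrow(partition)) {
    stop_validation("matrix size and partition size differ")
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_validation(sprintf(
      "non-finite entry at [%d, %d]", bad[1, 1], bad[1, 2]
    ))
  }
  asym <- abs(values - t(values))
  if (max(asym) > tol_asymmetry) {
    cell <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop_validation(sprintf(
      "asymmetry %.3g at [%d, %d] exceeds tolerance %.3g",
      max(asym), cell[1], cell[2], tol_asymmetry
    ))
  }
  values <- (values + t(values)) / 2
  diag(values) <- 1
  out <- structure(
    list(values = values, partition = partition, params = list(source = "user")),
    class = "ground_truth"
  )
  validate_groundtruth(out)
}

validate_groundtruth <- function(gt, structure = TRUE) {
  w <- gt$values
  off <- ut_values(w)
  bad <- which(abs(w) > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_validation(sprintf(
      "|correlation| > 1 at [%d, %d]: %.4f", bad[1, 1], bad[1, 2], w[bad[1, , drop = FALSE]]
    ))
  }
  if (any(abs(diag(w) - 1) > 1e-12)) {
    stop_validation("diagonal must be exactly 1")
  }
  if (structure) {
    if (mean(off) <= 0) {
      stop_validation("mean off-diagonal FC must be positive")
    }
    mod <- module_ids(gt$partition)
    pairs <- upper_pairs(nrow(w))
    same <- mod[pairs[, "i"]] == mod[pairs[, "j"]]
    if (mean(off[same]) <= mean(off[!same])) {
      stop_validation("mean within-module FC must exceed mean between-module FC")
    }
  }
  gt
}

#' Summary statistics of a groundtruth matrix
#'
#' @param gt A `ground_truth` object.
#' @param r_ref Reference cutoff for the edge-proportion column.
#' @return A one-row tibble: node count, mean/SD of off-diagonal FC, mean
#'   within- and between-module FC, proportion of edges above `r_ref`, and
#'   sample skewness of node strength.
#' @export
fc_summary <- function(gt, r_ref = 0.2) {
  w <- gt$values
  off <- ut_values(w)
  mod <- module_ids(gt$partition)
  pairs <- upper_pairs(nrow(w))
  same <- mod[pairs[, "i"]] == mod[pairs[, "j"]]
  strength <- colSums(pmax(w, 0)) - 1
  m <- mean(strength); s <- sd(strength)
  skew <- mean((strength - m)^3) / (mean((strength - m)^2))^1.5
  tibble(
    n_nodes = nrow(w),
    mean_fc = mean(off),
    sd_fc = sd(off),
    mean_within = mean(off[same]),
    mean_between = mean(off[!same]),
    prop_above_ref = mean(off > r_ref),
    strength_skewness = skew
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d nodes, %d modules\n",
    nrow(x$values), nlevels(x$partition$module)
  ))
  print(fc_summary(x))
  invisible(x)
}
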