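#' Build a node-to-module partition
#'
#' Assigns `n_nodes` nodes to contiguous module blocks. With no sizes given,
#' the 264-node default mimics the relative module sizes of a canonical
#' 13-community functional parcellation (a large default-mode network, a large
#' visual network, mid-sized fronto-parietal and attention networks, several
#' small systems); for other `n_nodes` the nodes are split into
#' equal-as-possible blocks.
#'
#' @param n_nodes Number of nodes.
#' @param module_sizes Optional integer vector of module sizes; must sum to
#'   `n_nodes`, all sizes >= 1.
#' @param module_names Optional character vector of unique labels, one per
#'   module. Defaults to the canonical names for the 264/13 case and to
#'   `M01, M02, ...` otherwise.
#' @param n_modules Number of modules when `module_sizes` is `NULL`.
#' @return A tibble of class `module_partition` with columns `node` (integer)
#'   and `module` (factor, levels in block order).
#' @examples
#' generate_partition(6, module_sizes = c(3, 3))
#' @export
generate_partition <- function(n_nodes = 264, module_sizes = NULL,
                               module_names = NULL, n_modules = 13) {
  if (is.null(module_sizes)) {
    if (n_nodes == 264 && n_modules == 13) {
      # the three manipulated systems are sized so that the default
      # case-control modular design covers equal edge counts per group
      # (DMN = FPN + DAN), keeping the two groups' modulation levels similar
      module_sizes <- c(41, 14, 13, 36, 5, 31, 25, 18, 13, 15, 11, 4, 38)
      module_names <- module_names %||% c(
        "Somatomotor", "CinguloOpercular", "Auditory", "DMN", "Memory",
        "Visual", "FPN", "Salience", "Subcortical", "VAN", "DAN",
        "Cerebellar", "Uncertain"
      )
    } else {
      base <- n_nodes %/% n_modules
      module_sizes <- rep.int(base, n_modules) +
        c(rep.int(1L, n_nodes %% n_modules), rep.int(0L, n_modules - n_nodes %% n_modules))
    }
  }
  module_sizes <- as.integer(module_sizes)
  if (any(module_sizes < 1L)) {
    stop_config("all module sizes must be >= 1")
  }
  if (sum(module_sizes) != n_nodes) {
    stop_config(sprintf(
      "module sizes sum to %d but n_nodes is %d", sum(module_sizes), n_nodes
    ))
  }
  k <- length(module_sizes)
  module_names <- module_names %||% sprintf("M%02d", seq_len(k))
  if (length(module_names) != k || anyDuplicated(module_names)) {
    stop_config("module_names must be unique and match the number of modules")
  }
  out <- tibble(
    node = seq_len(n_nodes),
    module = factor(rep(module_names, times = module_sizes), levels = module_names)
  )
  class(out) <- c("module_partition", class(out))
  out
}

#' Coerce a data frame to a module partition
#'
#' @param x A data frame with columns `node` and `module`.
#' @return A validated `module_partition` tibble.
#' @export
as_partition <- function(x) {
  if (inherits(x, "module_partition")) return(validate_partition(x))
  if (!all(c("node", "module") %in% names(x))) {
    stop_validation("a partition needs `node` and `module` columns")
  }
  out <- as_tibble(x)
  out$node <- as.integer(out$node)
  if (!is.factor(out$module)) out$module <- factor(out$module, levels = unique(out$module))
  out <- out[order(out$node), c("node", "module")]
  class(out) <- c("module_partition", class(out))
  validate_partition(out)
}

validate_partition <- function(partition) {
  if (anyDuplicated(partition$node) || any(is.na(partition$module))) {
    stop_validation("every node must carry exactly one module label")
  }
  if (!identical(partition$node, seq_along(partition$node))) {
    stop_validation("partition nodes must be the consecutive integers 1..N")
  }
  if (any(table(partition$module) == 0)) {
    stop_validation("every module must be non-empty")
  }
  partition
}

# integer module id per node, plus label lookup
module_ids <- function(partition) as.integer(partition$module)

# node indices belonging to the given module labels
module_nodes <- function(partition, labels) {
  missing <- setdiff(labels, levels(partition$module))
  if (length(missing) > 0) {
    stop_design(sprintf(
      "partition has no module(s): %s", paste(missing, collapse = ", ")
    ))
  }
  partition$node[partition$module %in% labels]
}
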