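# Multilevel subject model. For each unordered node pair i < j the simulated
# edge is
#   r_ijs = w_ij + (b_s + u_ijs) + alpha_ijs + e_ijs
# with b_s drawn once per subject, u and e per edge, and the targeted shift
# alpha_ijs = a_is + v_ijs applied only to manipulations of the subject's
# group, only within each manipulation's edge scope, and at most once per
# unordered pair (no compounding: once an edge has been shifted, later targets
# and manipulations skip it). Values are clipped to [-0.999, 0.999] and the
# clip count is recorded.

# precompute everything about the groundtruth/design that is constant across
# subjects: pair indices, scope masks, per-target incident-edge lists, and the
# hub-average strength used to scale proportional shifts
sim_context <- function(groundtruth, design) {
  w <- groundtruth$values
  n <- nrow(w)
  for (m in design$manipulations) {
    if (any(m$target_nodes > n)) {
      stop_design(sprintf("manipulation '%s' targets nodes beyond N = %d", m$label, n))
    }
  }
  pairs <- upper_pairs(n)
  w_ut <- ut_values(w)
  mod <- module_ids(groundtruth$partition)
  same <- mod[pairs[, "i"]] == mod[pairs[, "j"]]
  # incident edges per node, as indices into the upper-tri vector
  node_of <- c(pairs[, "i"], pairs[, "j"])
  edge_of <- rep.int(seq_len(nrow(pairs)), 2L)
  incident <- split(edge_of, node_of)

  strength <- colSums(abs(w)) - 1
  hubs <- order(strength, decreasing = TRUE)[seq_len(max(1L, round(0.1 * n)))]
  hub_edges <- unique(unlist(incident[as.character(hubs)], use.names = FALSE))
  w_ref <- mean(abs(w_ut[hub_edges]))

  manip_edges <- lapply(design$manipulations, function(m) {
    # "within" covers edges internal to the targeted system: same-module
    # pairs plus pairs joining two targeted nodes (e.g. FPN-DAN pairs when
    # both networks are targeted together). "between" reaches from the
    # target set to *other* networks only: different-module pairs that are
    # not internal to the set. The two scopes partition a target's edges.
    in_set <- pairs[, "i"] %in% m$target_nodes & pairs[, "j"] %in% m$target_nodes
    scope_ok <- switch(m$edge_scope,
                       all = rep.int(TRUE, length(w_ut)),
                       within = same | in_set,
                       between = !same & !in_set)
    lapply(m$target_nodes, function(t) {
      e <- incident[[as.character(t)]]
      e[scope_ok[e]]
    })
  })
  list(
    n = n, w_ut = w_ut, pairs = pairs, same_module = same,
    manip_edges = manip_edges, w_ref = w_ref
  )
}

# draw one subject's upper-triangle values; RNG state is the caller's
sim_subject_values <- function(ctx, design, group) {
  m_edges <- length(ctx$w_ut)
  ns <- design$noise
  b_s <- rnorm(1, 0, ns$sigma_b)
  r <- ctx$w_ut + b_s + rnorm(m_edges, 0, ns$sigma_w) + rnorm(m_edges, 0, ns$sigma_e)
  taken <- logical(m_edges)
  for (k in seq_along(design$manipulations)) {
    mp <- design$manipulations[[k]]
    if (mp$group != group) next
    a_vals <- rnorm(length(mp$target_nodes), mp$mu_a, mp$sigma_a)
    for (t in seq_along(mp$target_nodes)) {
      edges <- ctx$manip_edges[[k]][[t]]
      free <- edges[!taken[edges]]
      if (length(free) == 0) next
      shift <- a_vals[t] + rnorm(length(free), 0, mp$sigma_v)
      if (mp$mode == "proportional") {
        r[free] <- r[free] + ctx$w_ut[free] * (shift / ctx$w_ref)
      } else {
        r[free] <- r[free] + shift
      }
      taken[free] <- TRUE
    }
  }
  n_clipped <- sum(r > 0.999 | r < -0.999)
  if (n_clipped > 0) r <- pmin(pmax(r, -0.999), 0.999)
  list(values_ut = r, b_s = b_s, n_clipped = n_clipped)
}

#' Simulate one subject's adjacency matrix
#'
#' Draws a single subject from the multilevel model around the groundtruth.
#' Uses the current RNG state; seed management (per-replication substreams)
#' is handled by [simulate_cohort()].
#'
#' @param groundtruth A `ground_truth` object.
#' @param design An [experiment_design()].
#' @param group `"patient"` or `"control"`.
#' @param subject_id Identifier stored on the result.
#' @return A `subject_matrix`: list with `values` (symmetric N x N matrix,
#'   unit diagonal), `group`, `subject_id`, `b_s` (realized person-level
#'   offset), and `n_clipped`.
#' @export
simulate_subject <- function(groundtruth, design, group = c("patient", "control"),
                             subject_id = "S001") {
  group <- match.arg(group)
  ctx <- sim_context(groundtruth, design)
  drawn <- sim_subject_values(ctx, design, group)
  structure(
    list(
      values = ut_to_matrix(drawn$values_ut, ctx$n),
      group = group, subject_id = subject_id,
      b_s = drawn$b_s, n_clipped = drawn$n_clipped
    ),
    class = "subject_matrix"
  )
}

#' Simulate a full case-control cohort
#'
#' Simulates `n_patients` + `n_controls` subjects. The RNG substream is
#' derived deterministically from `(design$seed, replication_id)`, so any
#' replication can be re-created independently of the others.
#'
#' @param groundtruth A `ground_truth` object.
#' @param design An [experiment_design()].
#' @param replication_id Replication sample index (>= 1).
#' @return A `cohort`: list with `subjects` (patients first, then controls),
#'   `design`, `replication_id`, and `n_clipped` (total clip count).
#' @export
simulate_cohort <- function(groundtruth, design, replication_id = 1) {
  ctx <- sim_context(groundtruth, design)
  set_substream(design$seed, replication_id, 31L)
  groups <- c(rep("patient", design$n_patients), rep("control", design$n_controls))
  ids <- c(sprintf("P%03d", seq_len(design$n_patients)),
           sprintf("C%03d", seq_len(design$n_controls)))
  subjects <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    drawn <- sim_subject_values(ctx, design, groups[s])
    subjects[[s]] <- structure(
      list(values = ut_to_matrix(drawn$values_ut, ctx$n), group = groups[s],
           subject_id = ids[s], b_s = drawn$b_s, n_clipped = drawn$n_clipped),
      class = "subject_matrix"
    )
  }
  structure(
    list(
      subjects = subjects, design = design, replication_id = replication_id,
      n_clipped = sum(vapply(subjects, function(x) x$n_clipped, numeric(1)))
    ),
    class = "cohort"
  )
}

# fast path for the experiment drivers: upper-tri value matrix (edges x
# subjects) without materializing per-subject square matrices
sim_cohort_ut <- function(ctx, design, replication_id) {
  set_substream(design$seed, replication_id, 31L)
  groups <- c(rep("patient", design$n_patients), rep("control", design$n_controls))
  v <- matrix(0, length(ctx$w_ut), length(groups))
  b <- numeric(length(groups))
  clipped <- 0
  for (s in seq_along(groups)) {
    drawn <- sim_subject_values(ctx, design, groups[s])
    v[, s] <- drawn$values_ut
    b[s] <- drawn$b_s
    clipped <- clipped + drawn$n_clipped
  }
  list(values = v, group = groups, b_s = b, n_clipped = clipped)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> replication %d: %d patients + %d controls (clipped edges: %d)\n",
    x$replication_id, x$design$n_patients, x$design$n_controls, x$n_clipped
  ))
  invisible(x)
}

# accept a subject_matrix, ground_truth, or plain symmetric matrix
as_fc_matrix <- function(x) {
  if (inherits(x, "subject_matrix") || inherits(x, "ground_truth")) return(x$values)
  if (is.matrix(x) && nrow(x) == ncol(x)) return(x)
  stop_validation("expected a subject_matrix, ground_truth, or square matrix")
}
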