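#' Noise parameters of the multilevel subject model
#'
#' Three unsystematic variance sources perturb the groundtruth for every
#' simulated subject: `sigma_b`, the SD of the person-level offset added to
#' every edge (between-person variation in mean FC); `sigma_w`, the SD of
#' edgewise within-person variation around that offset; and `sigma_e`, the SD
#' of residual edge noise. All are in correlation units.
#'
#' Defaults were fixed analytically before any experiment was run, by matching
#' the expected sensitivity of the weighted (unthresholded) strength analysis
#' to its published operating anchors; the methods vignette derives them.
#'
#' @param sigma_b,sigma_w,sigma_e Non-negative SDs in correlation units.
#' @return A `noise_params` list.
#' @export
noise_params <- function(sigma_b = 0.11, sigma_w = 0.09, sigma_e = 0.09) {
  if (any(c(sigma_b, sigma_w, sigma_e) < 0)) {
    stop_config("noise SDs must be non-negative")
  }
  structure(
    list(sigma_b = sigma_b, sigma_w = sigma_w, sigma_e = sigma_e),
    class = "noise_params"
  )
}

#' Describe a targeted FC shift on a set of nodes
#'
#' A manipulation shifts the FC of every edge incident to its target nodes
#' (restricted by `edge_scope`) in one group. The realized shift for node `i`
#' in subject `s` is `a_is + v_ijs`, with `a_is ~ N(mu_a, sigma_a)` drawn once
#' per subject-node and `v_ijs ~ N(0, sigma_v)` drawn per edge, so shifts vary
#' both across people and across a node's neighbors. In `proportional` mode
#' the additive shift is converted to a multiplicative perturbation of the
#' groundtruth weight with matched expected magnitude at hub-average strength,
#' so stronger edges change more and zero-strength edges not at all.
#'
#' @param target_nodes Integer node indices receiving the shift.
#' @param mu_a Mean FC shift (correlation units; sign gives direction).
#' @param sigma_a Between-person SD of the node-level shift.
#' @param sigma_v Within-person SD of the shift across a node's edges.
#' @param group Which group receives the manipulation.
#' @param mode `additive` (shift in correlation units) or `proportional`
#'   (multiplicative in groundtruth strength).
#' @param edge_scope Which incident edges are eligible: `all`; `within` --
#'   edges internal to the targeted system (same-module pairs plus pairs
#'   joining two targeted nodes); or `between` -- edges from the target set
#'   to other networks (different-module pairs not internal to the set).
#' @param label Optional label used in result tables (e.g. "Positive").
#' @return A `node_manipulation` list.
#' @export
node_manipulation <- function(target_nodes, mu_a, sigma_a = 0.05, sigma_v = 0.05,
                              group = c("patient", "control"),
                              mode = c("additive", "proportional"),
                              edge_scope = c("all", "within", "between"),
                              label = NULL) {
  group <- match.arg(group)
  mode <- match.arg(mode)
  edge_scope <- match.arg(edge_scope)
  target_nodes <- as.integer(target_nodes)
  if (length(target_nodes) == 0 || anyDuplicated(target_nodes)) {
    stop_design("target_nodes must be a non-empty set of distinct node indices")
  }
  if (sigma_a < 0 || sigma_v < 0) stop_config("sigma_a and sigma_v must be non-negative")
  structure(
    list(
      target_nodes = target_nodes, mu_a = mu_a, sigma_a = sigma_a,
      sigma_v = sigma_v, group = group, mode = mode, edge_scope = edge_scope,
      label = label %||% sprintf("shift%+0.2f", mu_a)
    ),
    class = "node_manipulation"
  )
}

#' Declare a full case-control simulation design
#'
#' One `experiment_design` fully determines a replication sample: cohort
#' sizes, the unsystematic noise levels, the targeted manipulations, and the
#' master seed from which all replication substreams are derived.
#'
#' @param n_patients,n_controls Group sizes (>= 2).
#' @param noise A [noise_params()] object.
#' @param manipulations List of [node_manipulation()] objects. Manipulations
#'   of the same group whose edge scopes can overlap must have disjoint target
#'   sets; within/between pairs may share targets because their edge sets are
#'   disjoint by construction.
#' @param n_replications Number of replication samples (>= 1).
#' @param seed Master integer seed.
#' @param node_classes Optional named list of node-index sets tracked in
#'   downstream result tables (e.g. Positive/Negative/Comparator).
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(n_patients = 50, n_controls = 50,
                              noise = noise_params(), manipulations = list(),
                              n_replications = 100, seed = 1,
                              node_classes = NULL) {
  if (n_patients < 2 || n_controls < 2) stop_design("group sizes must be >= 2")
  if (n_replications < 1) stop_design("n_replications must be >= 1")
  stopifnot(inherits(noise, "noise_params"))
  for (m in manipulations) stopifnot(inherits(m, "node_manipulation"))
  for (grp in c("patient", "control")) {
    ms <- Filter(function(m) m$group == grp, manipulations)
    if (length(ms) > 1) {
      for (a in seq_along(ms)) {
        for (b in seq_len(a - 1)) {
          scopes <- c(ms[[a]]$edge_scope, ms[[b]]$edge_scope)
          overlap_possible <- "all" %in% scopes || scopes[1] == scopes[2]
          shared <- intersect(ms[[a]]$target_nodes, ms[[b]]$target_nodes)
          if (overlap_possible && length(shared) > 0) {
            stop_design(sprintf(
              "manipulations '%s' and '%s' for group %s share target node(s) %s",
              ms[[a]]$label, ms[[b]]$label, grp,
              paste(utils::head(shared, 5), collapse = ", ")
            ))
          }
        }
      }
    }
  }
  structure(
    list(
      n_patients = n_patients, n_controls = n_controls, noise = noise,
      manipulations = manipulations, n_replications = n_replications,
      seed = seed, node_classes = node_classes
    ),
    class = "experiment_design"
  )
}

#' Design of the whack-a-node experiment
#'
#' Draws three pairwise-disjoint node sets uniformly at random: `Positive`
#' nodes receive a robust FC increase in patients (default +0.14), `Negative`
#' nodes a weak decrease (default -0.04, typically set by
#' [calibrate_negative_shift()]), and `Comparator` nodes are left untouched as
#' a benchmark. With `flipped = TRUE` the signs of both shifts are reversed
#' (robust hypoconnectivity plus weak hyperconnectivity); with
#' `proportional = TRUE` shifts multiply the groundtruth weight instead of
#' adding to it.
#'
#' @param groundtruth A `ground_truth` object.
#' @param shift_positive,shift_negative Mean shifts for the two targeted sets.
#' @param n_each Nodes per set.
#' @param flipped Reverse the sign of both shifts.
#' @param proportional Use proportional (strength-scaled) shifts.
#' @param sigma_a,sigma_v Between-person and within-node SDs of the shifts;
#'   `NULL` (default) sets each to half the manipulation's mean shift
#'   magnitude, the constant coefficient of variation that the modular
#'   experiment's stated parameters follow (SD = Mr / 2).
#' @param noise A [noise_params()] object.
#' @param n_patients,n_controls,n_replications,seed See [experiment_design()].
#' @return An `experiment_design` whose `node_classes` records the three sets.
#' @export
make_whack_design <- function(groundtruth, shift_positive = 0.14,
                              shift_negative = -0.04, n_each = 3,
                              flipped = FALSE, proportional = FALSE,
                              sigma_a = NULL, sigma_v = NULL,
                              noise = noise_params(),
                              n_patients = 50, n_controls = 50,
                              n_replications = 100, seed = 1) {
  n <- nrow(groundtruth$values)
  if (3 * n_each > n) {
    stop_design(sprintf("3 x n_each = %d exceeds the %d available nodes", 3 * n_each, n))
  }
  set_substream(seed, 23L)
  picked <- sample.int(n, 3 * n_each)
  sets <- list(
    Positive = sort(picked[seq_len(n_each)]),
    Negative = sort(picked[n_each + seq_len(n_each)]),
    Comparator = sort(picked[2 * n_each + seq_len(n_each)])
  )
  sgn <- if (flipped) -1 else 1
  mode <- if (proportional) "proportional" else "additive"
  sd_of <- function(given, mu) given %||% (abs(mu) / 2)
  manips <- list(
    node_manipulation(sets$Positive, sgn * shift_positive,
                      sd_of(sigma_a, shift_positive), sd_of(sigma_v, shift_positive),
                      group = "patient", mode = mode, label = "Positive"),
    node_manipulation(sets$Negative, sgn * shift_negative,
                      sd_of(sigma_a, shift_negative), sd_of(sigma_v, shift_negative),
                      group = "patient", mode = mode, label = "Negative")
  )
  experiment_design(
    n_patients = n_patients, n_controls = n_controls, noise = noise,
    manipulations = manips, n_replications = n_replications, seed = seed,
    node_classes = sets
  )
}

#' Design of the global-insensitivity experiment
#'
#' Two-tier modular manipulation mirroring canonical resting-state networks:
#' controls gain FC on the fronto-parietal (FPN) and dorsal attention (DAN)
#' networks -- edges from FPN/DAN nodes to other modules shifted by
#' `between_mu` (between-person SD `between_sigma_a`, within-person SD
#' `between_sigma_v`) and within-module FPN/DAN edges by `within_mu` (SDs
#' `within_sigma_a` / `within_sigma_v`) -- while patients receive the same
#' two-tier structure on default-mode (DMN) nodes. The Visual module is left
#' untouched as a comparator.
#'
#' @param groundtruth A `ground_truth` whose partition contains the labels in
#'   `control_modules`, `patient_modules`, and `comparator_module`.
#' @param between_mu,between_sigma_a,between_sigma_v Between-module tier.
#' @param within_mu,within_sigma_a,within_sigma_v Within-module tier.
#' @param control_modules,patient_modules,comparator_module Module labels.
#' @param noise A [noise_params()] object.
#' @param n_patients,n_controls,n_replications,seed See [experiment_design()].
#' @return An `experiment_design` with `node_classes` set to the focal modules.
#' @export
make_module_design <- function(groundtruth,
                               between_mu = 0.2, between_sigma_a = 0.1,
                               between_sigma_v = 0.1,
                               within_mu = 0.1, within_sigma_a = 0.05,
                               within_sigma_v = 0.05,
                               control_modules = c("FPN", "DAN"),
                               patient_modules = "DMN",
                               comparator_module = "Visual",
                               noise = noise_params(),
                               n_patients = 50, n_controls = 50,
                               n_replications = 100, seed = 1) {
  part <- groundtruth$partition
  ctrl_nodes <- module_nodes(part, control_modules)
  pat_nodes <- module_nodes(part, patient_modules)
  comp_nodes <- module_nodes(part, comparator_module)
  manips <- list(
    node_manipulation(ctrl_nodes, between_mu, between_sigma_a, between_sigma_v,
                      group = "control", edge_scope = "between",
                      label = "control-between"),
    node_manipulation(ctrl_nodes, within_mu, within_sigma_a, within_sigma_v,
                      group = "control", edge_scope = "within",
                      label = "control-within"),
    node_manipulation(pat_nodes, between_mu, between_sigma_a, between_sigma_v,
                      group = "patient", edge_scope = "between",
                      label = "patient-between"),
    node_manipulation(pat_nodes, within_mu, within_sigma_a, within_sigma_v,
                      group = "patient", edge_scope = "within",
                      label = "patient-within")
  )
  classes <- lapply(
    c(patient_modules, control_modules, comparator_module),
    function(lbl) module_nodes(part, lbl)
  )
  names(classes) <- c(patient_modules, control_modules, comparator_module)
  experiment_design(
    n_patients = n_patients, n_controls = n_controls, noise = noise,
    manipulations = manips, n_replications = n_replications, seed = seed,
    node_classes = classes
  )
}

#' Serialize an experiment design to YAML
#'
#' @param design An `experiment_design`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
design_to_yaml <- function(design, path) {
  x <- list(
    n_patients = design$n_patients, n_controls = design$n_controls,
    noise = unclass(design$noise),
    manipulations = lapply(design$manipulations, unclass),
    n_replications = design$n_replications, seed = design$seed,
    node_classes = design$node_classes
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read an experiment design from YAML
#'
#' @param path YAML file written by [design_to_yaml()].
#' @return An `experiment_design`.
#' @export
design_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  experiment_design(
    n_patients = x$n_patients, n_controls = x$n_controls,
    noise = do.call(noise_params, x$noise),
    manipulations = lapply(x$manipulations, function(m) do.call(node_manipulation, m)),
    n_replications = x$n_replications, seed = x$seed,
    node_classes = lapply(x$node_classes, as.integer)
  )
}
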