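#' Run the global-insensitivity experiment
#'
#' Simulates case-control cohorts under the modular design of
#' [make_module_design()] (controls gain FC on FPN/DAN, patients on the DMN),
#' thresholds each subject proportionally across `densities`, and contrasts a
#' global statistic against nodal-modular ones: per subject and density it
#' computes small-worldness sigma (against `n_null` degree-preserving rewired
#' nulls) and within/between-module degree for the focal modules, z-scored
#' within each module x density x replication stratum.
#'
#' @param groundtruth A `ground_truth` whose partition carries the focal
#'   module labels.
#' @param n_replications Number of replication samples.
#' @param densities Proportional-threshold density grid.
#' @param n_null Null-ensemble size per sigma evaluation.
#' @param swaps_per_edge Rewiring effort per edge.
#' @param report_densities Densities highlighted in the module-degree summary.
#' @param noise A [noise_params()] object.
#' @param design_args Named list of overrides passed to [make_module_design()]
#'   (shift means/SDs, module labels, group sizes).
#' @param negative_policy Negative-edge policy applied before thresholding.
#' @param var_method Two-sample variance treatment.
#' @param seed Master seed.
#' @param progress Print a line per replication.
#' @return A `global_result` with `sigma_results` (subject-level sigma),
#'   `sigma_by_density` (per-density group t summary), `sigma_mean_t`,
#'   `module_results` (node-level z-scored within/between degree for focal
#'   modules), `module_summary` (group contrasts at `report_densities`),
#'   `within_regression` / `between_regression` ([module_group_regression()]
#'   fits), and `params`.
#' @export
run_global_insensitivity <- function(groundtruth, n_replications = 20,
                                     densities = c(0.075, 0.10, 0.15, 0.20, 0.25),
                                     n_null = 10, swaps_per_edge = 10,
                                     report_densities = c(0.10, 0.20),
                                     noise = noise_params(),
                                     design_args = list(),
                                     negative_policy = "discard",
                                     var_method = "welch",
                                     seed = 1, progress = FALSE) {
  if (any(densities <= 0 | densities > 1)) stop_config("densities must be in (0, 1]")
  design <- do.call(make_module_design, c(
    list(groundtruth = groundtruth, noise = noise,
         n_replications = n_replications, seed = seed),
    design_args
  ))
  ctx <- sim_context(groundtruth, design)
  n <- ctx$n
  focal <- design$node_classes
  focal_nodes <- unlist(focal, use.names = FALSE)
  focal_module <- rep(names(focal), lengths(focal))
  m_all <- nrow(ctx$pairs)

  sigma_rows <- vector("list", n_replications)
  degree_rows <- vector("list", n_replications)

  for (r in seq_len(n_replications)) {
    cohort <- sim_cohort_ut(ctx, design, replication_id = r)
    values <- apply_negative_policy(cohort$values, negative_policy)
    n_subj <- ncol(values)
    sig <- vector("list", n_subj * length(densities))
    deg <- vector("list", n_subj * length(densities))
    k <- 0
    for (s in seq_len(n_subj)) {
      v <- values[, s]
      ord <- order(-v, ctx$pairs[, "i"], ctx$pairs[, "j"])
      n_eligible <- if (negative_policy == "discard") sum(v > 0) else m_all
      for (d in seq_along(densities)) {
        m_keep <- min(round(densities[d] * m_all), n_eligible)
        keep <- ord[seq_len(m_keep)]
        same <- ctx$same_module[keep]
        iw <- ctx$pairs[keep[same], , drop = FALSE]
        ib <- ctx$pairs[keep[!same], , drop = FALSE]
        within_deg <- tabulate(c(iw[, 1], iw[, 2]), n)
        between_deg <- tabulate(c(ib[, 1], ib[, 2]), n)
        set_substream(seed, 71L, r, s, d)
        sw <- sigma_from_edges(ctx$pairs[keep, , drop = FALSE], n, n_null,
                               swaps_per_edge, "edges")
        k <- k + 1
        sig[[k]] <- tibble(
          replication = r, subject = s, group = cohort$group[s],
          density = densities[d], sigma = sw$sigma, c_g = sw$c_g, l_g = sw$l_g,
          c_rand = sw$c_rand, l_rand = sw$l_rand,
          component_coverage = sw$component_coverage
        )
        deg[[k]] <- tibble(
          replication = r, subject = s, group = cohort$group[s],
          density = densities[d], node = focal_nodes, module = focal_module,
          within_degree = within_deg[focal_nodes],
          between_degree = between_deg[focal_nodes]
        )
      }
    }
    sigma_rows[[r]] <- bind_rows(sig)
    degree_rows[[r]] <- bind_rows(deg)
    if (progress) {
      message(sprintf("global insensitivity: replication %d / %d", r, n_replications))
    }
  }

  sigma_results <- bind_rows(sigma_rows)
  module_results <- bind_rows(degree_rows)

  # z-score module degree within each replication x density x module stratum
  module_results <- module_results %>%
    zscore_by_module_density(value = "within_degree",
                             strata = c("replication", "density", "module")) %>%
    rename(z_within = "z", zero_var_within = "zero_variance") %>%
    zscore_by_module_density(value = "between_degree",
                             strata = c("replication", "density", "module")) %>%
    rename(z_between = "z", zero_var_between = "zero_variance")

  # per-density group comparison of sigma, averaged over replications
  sigma_tests <- sigma_results %>%
    rename(value = "sigma") %>%
    mutate(node = 1L) %>%
    select("replication", "density", "node", "group", "value") %>%
    nodewise_t_tests(var_method = var_method) %>%
    select(-"node")
  sigma_by_density <- sigma_tests %>%
    group_by(.data$density) %>%
    summarise(mean_t = mean(.data$t), sd_t = sd(.data$t), mean_p = mean(.data$p),
              .groups = "drop")

  within_regression <- module_group_regression(
    module_results %>% rename(z = "z_within")
  )
  between_regression <- module_group_regression(
    module_results %>% rename(z = "z_between")
  )

  module_summary <- module_results %>%
    filter(.data$density %in% report_densities) %>%
    tidyr::pivot_longer(c("z_within", "z_between"),
                        names_to = "scope", values_to = "z") %>%
    mutate(scope = ifelse(.data$scope == "z_within", "within", "between")) %>%
    group_by(.data$density, .data$module, .data$scope) %>%
    summarise(
      mean_z_patient = mean(.data$z[.data$group == "patient"]),
      mean_z_control = mean(.data$z[.data$group == "control"]),
      diff = mean(.data$z[.data$group == "patient"]) -
        mean(.data$z[.data$group == "control"]),
      .groups = "drop"
    )

  structure(
    list(
      sigma_results = sigma_results,
      sigma_tests = sigma_tests,
      sigma_by_density = sigma_by_density,
      sigma_mean_t = mean(sigma_tests$t),
      module_results = module_results,
      module_summary = module_summary,
      within_regression = within_regression,
      between_regression = between_regression,
      params = list(
        n_replications = n_replications, densities = densities,
        n_null = n_null, swaps_per_edge = swaps_per_edge,
        report_densities = report_densities, noise = unclass(noise),
        design_args = design_args, negative_policy = negative_policy,
        var_method = var_method, seed = seed, n_nodes = n
      )
    ),
    class = "global_result"
  )
}

#' @export
print.global_result <- function(x, ...) {
  cat(sprintf(
    "<global_result> %d replications, %d-node groundtruth\n",
    x$params$n_replications, x$params$n_nodes
  ))
  cat(sprintf("mean group-difference t on sigma: %.3f\n", x$sigma_mean_t))
  print(x$sigma_by_density)
  cat("patient-minus-control effects on z-scored within-module degree:\n")
  print(tidy(x$within_regression))
  invisible(x)
}

#' @describeIn run_global_insensitivity Per-module patient effects on z-scored
#'   within- and between-module degree.
#' @param x A `global_result`.
#' @param ... Unused.
#' @export
tidy.global_result <- function(x, ...) {
  bind_rows(
    mutate(tidy(x$within_regression), scope = "within"),
    mutate(tidy(x$between_regression), scope = "between")
  )
}

#' @export
glance.global_result <- function(x, ...) {
  tibble(
    sigma_mean_t = x$sigma_mean_t,
    n_replications = x$params$n_replications,
    n_null = x$params$n_null,
    n_nodes = x$params$n_nodes,
    seed = x$params$seed
  )
}

#' Export a global-insensitivity result bundle as tidy TSVs plus a manifest
#'
#' @param result A `global_result`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_global_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$sigma_results, file.path(dir, "sigma_results.tsv"))
  readr::write_tsv(result$sigma_by_density, file.path(dir, "sigma_by_density.tsv"))
  readr::write_tsv(result$module_results, file.path(dir, "module_results.tsv"))
  readr::write_tsv(result$module_summary, file.path(dir, "module_summary.tsv"))
  readr::write_tsv(tidy(result), file.path(dir, "module_regressions.tsv"))
  yaml::write_yaml(result$params, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
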