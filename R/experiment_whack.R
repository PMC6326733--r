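#' Run the whack-a-node experiment
#'
#' Simulates `n_replications` case-control samples in which three randomly
#' drawn nodes are robustly hyperconnected in patients (Positive), three are
#' weakly hypoconnected (Negative), and three are untouched (Comparator), and
#' evaluates patient-minus-control differences under four analysis arms on the
#' *same* cohorts: degree under proportional thresholding across the density
#' grid (`pt`), degree under absolute FC thresholding across the cutoff grid
#' (`absolute`), the same absolute-threshold degree with per-subject graph
#' density as covariate (`absolute_density`), and strength on weighted graphs
#' (`weighted`).
#'
#' The targeted node sets are redrawn independently in every replication, so
#' replication-averaged statistics are not tied to particular nodes.
#'
#' @param groundtruth A `ground_truth` object.
#' @param n_replications Number of replication samples.
#' @param densities Proportional-threshold density grid.
#' @param r_cutoffs Absolute-threshold correlation grid.
#' @param shift_positive,shift_negative,n_each,flipped,proportional,sigma_a,sigma_v
#'   See [make_whack_design()]. `shift_negative` is typically the output of
#'   [calibrate_negative_shift()].
#' @param noise A [noise_params()] object.
#' @param n_patients,n_controls Group sizes.
#' @param negative_policy Negative-edge policy applied before thresholding.
#' @param var_method Two-sample variance treatment.
#' @param arms Analysis arms to run.
#' @param seed Master seed; every replication derives its own substream.
#' @param progress Print a line every 10 replications.
#' @return A `whack_result`: `results` (one row per replication x arm x
#'   cutoff x tracked node), `aggregate` and `aggregate_by_cutoff` summaries,
#'   `pt_regression` / `absolute_regression` (threshold regressions), and
#'   `params` (including total clip count and a config hash).
#' @export
run_whack_a_node <- function(groundtruth, n_replications = 100,
                             densities = seq(0.05, 0.25, by = 0.01),
                             r_cutoffs = seq(0.20, 0.50, by = 0.02),
                             shift_positive = 0.14, shift_negative = -0.04,
                             n_each = 3, flipped = FALSE, proportional = FALSE,
                             sigma_a = NULL, sigma_v = NULL,
                             noise = noise_params(),
                             n_patients = 50, n_controls = 50,
                             negative_policy = "discard",
                             var_method = "welch",
                             arms = c("pt", "absolute", "absolute_density", "weighted"),
                             seed = 1, progress = FALSE) {
  arms <- match.arg(arms, several.ok = TRUE)
  if (any(densities <= 0 | densities > 1)) stop_config("densities must be in (0, 1]")
  if (any(abs(r_cutoffs) >= 1)) stop_config("r_cutoffs must satisfy |r| < 1")
  n <- nrow(groundtruth$values)
  rows <- vector("list", n_replications)
  n_clipped <- 0

  for (r in seq_len(n_replications)) {
    design <- make_whack_design(
      groundtruth, shift_positive = shift_positive,
      shift_negative = shift_negative, n_each = n_each, flipped = flipped,
      proportional = proportional, sigma_a = sigma_a, sigma_v = sigma_v,
      noise = noise, n_patients = n_patients, n_controls = n_controls,
      n_replications = 1, seed = substream_seed(seed, 51L, r)
    )
    ctx <- sim_context(groundtruth, design)
    cohort <- sim_cohort_ut(ctx, design, replication_id = r)
    n_clipped <- n_clipped + cohort$n_clipped
    is_patient <- cohort$group == "patient"
    values <- apply_negative_policy(cohort$values, negative_policy)

    tracked <- design$node_classes
    tracked_nodes <- unlist(tracked, use.names = FALSE)
    tracked_class <- rep(names(tracked), lengths(tracked))
    rep_rows <- list()

    if (any(c("pt", "absolute", "absolute_density") %in% arms)) {
      n_subj <- ncol(values)
      pt_deg <- array(0, c(n, length(densities), n_subj))
      abs_deg <- array(0, c(n, length(r_cutoffs), n_subj))
      abs_density <- matrix(0, length(r_cutoffs), n_subj)
      for (s in seq_len(n_subj)) {
        v <- values[, s]
        if ("pt" %in% arms) {
          cts <- threshold_degree_counts(v, ctx$pairs, n, "proportional",
                                         densities, negative_policy)
          pt_deg[, , s] <- cts$degrees
        }
        if (any(c("absolute", "absolute_density") %in% arms)) {
          cts <- threshold_degree_counts(v, ctx$pairs, n, "absolute",
                                         r_cutoffs, negative_policy)
          abs_deg[, , s] <- cts$degrees
          abs_density[, s] <- cts$densities
        }
      }
      if ("pt" %in% arms) {
        for (d in seq_along(densities)) {
          res <- group_t_matrix(pt_deg[tracked_nodes, d, ], is_patient, var_method)
          rep_rows[[length(rep_rows) + 1]] <- tibble(
            replication = r, strategy = "pt", cutoff = densities[d],
            node = tracked_nodes, node_class = tracked_class,
            t = res$t, df = res$df, p = res$p
          )
        }
      }
      if ("absolute" %in% arms) {
        for (d in seq_along(r_cutoffs)) {
          res <- group_t_matrix(abs_deg[tracked_nodes, d, ], is_patient, var_method)
          rep_rows[[length(rep_rows) + 1]] <- tibble(
            replication = r, strategy = "absolute", cutoff = r_cutoffs[d],
            node = tracked_nodes, node_class = tracked_class,
            t = res$t, df = res$df, p = res$p
          )
        }
      }
      if ("absolute_density" %in% arms) {
        g <- as.numeric(is_patient)
        for (d in seq_along(r_cutoffs)) {
          y <- t(abs_deg[tracked_nodes, d, , drop = TRUE])
          dens <- abs_density[d, ]
          fit <- if (sd(dens) > 0) {
            multiresponse_coef_t(cbind(1, g, dens), y, 2L)
          } else {
            NULL
          }
          if (is.null(fit)) fit <- multiresponse_coef_t(cbind(1, g), y, 2L)
          rep_rows[[length(rep_rows) + 1]] <- tibble(
            replication = r, strategy = "absolute_density",
            cutoff = r_cutoffs[d], node = tracked_nodes,
            node_class = tracked_class, t = fit$t, df = fit$df, p = fit$p
          )
        }
      }
    }
    if ("weighted" %in% arms) {
      strengths <- node_strengths_ut(ctx, values)
      res <- group_t_matrix(strengths[tracked_nodes, , drop = FALSE],
                            is_patient, var_method)
      rep_rows[[length(rep_rows) + 1]] <- tibble(
        replication = r, strategy = "weighted", cutoff = NA_real_,
        node = tracked_nodes, node_class = tracked_class,
        t = res$t, df = res$df, p = res$p
      )
    }
    rows[[r]] <- bind_rows(rep_rows)
    if (progress && r %% 10 == 0) {
      message(sprintf("whack-a-node: replication %d / %d", r, n_replications))
    }
  }

  results <- bind_rows(rows)
  params <- list(
    n_replications = n_replications, densities = densities,
    r_cutoffs = r_cutoffs, shift_positive = shift_positive,
    shift_negative = shift_negative, n_each = n_each, flipped = flipped,
    proportional = proportional, sigma_a = sigma_a, sigma_v = sigma_v,
    noise = unclass(noise), n_patients = n_patients, n_controls = n_controls,
    negative_policy = negative_policy, var_method = var_method,
    arms = arms, seed = seed, n_clipped = n_clipped,
    n_nodes = n
  )
  params$config_hash <- rlang::hash(params[setdiff(names(params), "n_clipped")])

  pt_regression <- NULL
  absolute_regression <- NULL
  if ("pt" %in% arms && length(densities) >= 3 && n_replications >= 2) {
    pt_regression <- density_nodetype_regression(filter(results, .data$strategy == "pt"))
  }
  if ("absolute" %in% arms && length(r_cutoffs) >= 3 && n_replications >= 2) {
    absolute_regression <-
      density_nodetype_regression(filter(results, .data$strategy == "absolute"))
  }

  structure(
    list(
      results = results,
      aggregate = aggregate_replications(results, per_cutoff = FALSE),
      aggregate_by_cutoff = aggregate_replications(results, per_cutoff = TRUE),
      pt_regression = pt_regression,
      absolute_regression = absolute_regression,
      params = params
    ),
    class = "whack_result"
  )
}

#' @export
print.whack_result <- function(x, ...) {
  cat(sprintf(
    "<whack_result> %d replications, %d-node groundtruth (clipped edges: %d)\n",
    x$params$n_replications, x$params$n_nodes, x$params$n_clipped
  ))
  cat("replication-averaged group statistics (patient minus control):\n")
  print(x$aggregate)
  invisible(x)
}

#' @describeIn run_whack_a_node Replication-averaged summary table (one row
#'   per arm x node class).
#' @param x A `whack_result`.
#' @param ... Unused.
#' @export
tidy.whack_result <- function(x, ...) x$aggregate

#' @export
glance.whack_result <- function(x, ...) {
  tibble(
    n_replications = x$params$n_replications,
    n_nodes = x$params$n_nodes,
    n_clipped = x$params$n_clipped,
    seed = x$params$seed,
    config_hash = x$params$config_hash
  )
}

#' Export a whack-a-node result bundle as tidy TSVs plus a manifest
#'
#' Writes `results.tsv` (per-replication node statistics),
#' `aggregate.tsv` and `aggregate_by_cutoff.tsv` (replication-averaged
#' summaries with 10/50/90 percentile bands), slope tables for the threshold
#' regressions, and `manifest.yaml` (full provenance: parameters, seed, config
#' hash, clip counts).
#'
#' @param result A `whack_result`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_whack_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$results, file.path(dir, "results.tsv"))
  readr::write_tsv(result$aggregate, file.path(dir, "aggregate.tsv"))
  readr::write_tsv(result$aggregate_by_cutoff, file.path(dir, "aggregate_by_cutoff.tsv"))
  if (!is.null(result$pt_regression)) {
    readr::write_tsv(tidy(result$pt_regression), file.path(dir, "pt_regression.tsv"))
  }
  if (!is.null(result$absolute_regression)) {
    readr::write_tsv(tidy(result$absolute_regression),
                     file.path(dir, "absolute_regression.tsv"))
  }
  yaml::write_yaml(result$params, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
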