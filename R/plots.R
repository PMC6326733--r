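# ggplot2 methods for result objects. Plots mirror the experiment summaries:
# crossbars span the 10th-90th percentile of the replication-wise t statistics
# with the median as the midline; dashed guides mark t = 0 and the two-sided
# p = .05 critical values for the cohort sizes.

#' @importFrom ggplot2 autoplot ggplot aes geom_hline geom_point geom_errorbar
#'   facet_grid facet_wrap labs theme_minimal geom_crossbar position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot a whack-a-node result
#'
#' One panel per analysis arm; within each, the distribution of
#' patient-minus-control t statistics per node class across replications
#' (median, 10th and 90th percentiles), either pooled over the threshold grid
#' or at a few selected cutoffs.
#'
#' @param object A `whack_result`.
#' @param cutoffs Optional cutoff subset for the per-cutoff display; `NULL`
#'   pools each arm over its grid.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.whack_result <- function(object, cutoffs = NULL, ...) {
  df_total <- object$params$n_patients + object$params$n_controls - 2
  t_crit <- qt(0.975, df_total)
  if (is.null(cutoffs)) {
    dat <- object$aggregate
    p <- ggplot(dat, aes(x = .data$node_class, y = .data$t_p50)) +
      geom_crossbar(aes(ymin = .data$t_p10, ymax = .data$t_p90,
                        fill = .data$node_class), alpha = 0.6, width = 0.6) +
      facet_wrap(~strategy, nrow = 1)
  } else {
    dat <- filter(object$aggregate_by_cutoff,
                  is.na(.data$cutoff) | .data$cutoff %in% cutoffs)
    p <- ggplot(dat, aes(x = factor(.data$cutoff), y = .data$t_p50,
                         fill = .data$node_class)) +
      geom_crossbar(aes(ymin = .data$t_p10, ymax = .data$t_p90),
                    alpha = 0.6, width = 0.6,
                    position = position_dodge(width = 0.7)) +
      facet_wrap(~strategy, nrow = 1, scales = "free_x")
  }
  p +
    geom_hline(yintercept = 0, linewidth = 0.8) +
    geom_hline(yintercept = c(-t_crit, t_crit), linetype = "dashed",
               colour = "grey60") +
    labs(x = NULL, y = "group difference t (patient - control)",
         fill = "node class") +
    theme_minimal()
}

#' Plot a global-insensitivity result
#'
#' @param object A `global_result`.
#' @param which `"sigma"` for the group difference in small-worldness across
#'   densities, `"modules"` for z-scored module-degree group contrasts at the
#'   reporting densities.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.global_result <- function(object, which = c("sigma", "modules"), ...) {
  which <- match.arg(which)
  if (which == "sigma") {
    dat <- object$sigma_tests %>%
      group_by(.data$density) %>%
      summarise(
        t_p10 = stats::quantile(.data$t, 0.10, names = FALSE),
        t_p50 = stats::quantile(.data$t, 0.50, names = FALSE),
        t_p90 = stats::quantile(.data$t, 0.90, names = FALSE),
        .groups = "drop"
      )
    ggplot(dat, aes(x = factor(.data$density), y = .data$t_p50)) +
      geom_crossbar(aes(ymin = .data$t_p10, ymax = .data$t_p90),
                    fill = "grey80", width = 0.5) +
      geom_hline(yintercept = 0, linewidth = 0.8) +
      labs(x = "edge density", y = "group difference t in small-worldness") +
      theme_minimal()
  } else {
    dat <- tidyr::pivot_longer(
      object$module_summary, c("mean_z_patient", "mean_z_control"),
      names_to = "group", values_to = "mean_z"
    ) %>%
      mutate(group = sub("mean_z_", "", .data$group))
    ggplot(dat, aes(x = .data$module, y = .data$mean_z, colour = .data$group)) +
      geom_point(position = position_dodge(width = 0.5), size = 2) +
      geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
      facet_grid(scope ~ density) +
      labs(x = NULL, y = "mean z-scored module degree", colour = NULL) +
      theme_minimal()
  }
}
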