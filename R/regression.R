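# Multilevel regressions across thresholds: mixed models with a random
# intercept per replication sample, Wald inference on the fixed effects.

fixef_contrast <- function(model, weights_named) {
  b <- lme4::fixef(model)
  v <- as.matrix(stats::vcov(model))
  l <- setNames(numeric(length(b)), names(b))
  l[names(weights_named)] <- weights_named
  c(estimate = unname(sum(l * b)), se = unname(sqrt(drop(t(l) %*% v %*% l))))
}

#' Regression of group-difference t statistics on threshold by node class
#'
#' Fits `t ~ cutoff * node_class + (1 | replication)` and reports each class's
#' slope of the group-difference t statistic over the threshold grid (with
#' Wald 95% CIs) plus a Wald chi-square test of the cutoff x node-class
#' interaction. Cutoffs are used on their native scale (densities as
#' proportions, FC cutoffs in correlation units).
#'
#' @param results A tibble with columns `t`, `cutoff`, `node_class`, and
#'   `replication` spanning at least 3 cutoffs and 2 node classes.
#' @return A `threshold_regression` object; see [tidy()] and [glance()].
#' @export
density_nodetype_regression <- function(results) {
  needed <- c("t", "cutoff", "node_class", "replication")
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (dplyr::n_distinct(results$cutoff) < 3) {
    stop_validation(paste(
      "need >= 3 distinct cutoffs for a threshold regression;",
      "use nodewise summaries for single-threshold analyses"
    ))
  }
  if (dplyr::n_distinct(results$node_class) < 2) {
    stop_validation("need >= 2 node classes")
  }
  dat <- results %>%
    mutate(
      node_class = factor(.data$node_class),
      replication = factor(.data$replication)
    )
  model <- lme4::lmer(t ~ cutoff * node_class + (1 | replication), data = dat,
                      REML = TRUE)
  classes <- levels(dat$node_class)
  slopes <- purrr::map_dfr(classes, function(cl) {
    w <- c(cutoff = 1)
    if (cl != classes[1]) {
      w <- c(w, setNames(1, paste0("cutoff:node_class", cl)))
    }
    est <- fixef_contrast(model, w)
    tibble(
      node_class = cl, slope = est[["estimate"]], se = est[["se"]],
      conf_low = est[["estimate"]] - 1.96 * est[["se"]],
      conf_high = est[["estimate"]] + 1.96 * est[["se"]],
      t_value = est[["estimate"]] / est[["se"]]
    )
  })
  b <- lme4::fixef(model)
  v <- as.matrix(stats::vcov(model))
  int_idx <- grep("^cutoff:node_class", names(b))
  wald <- drop(t(b[int_idx]) %*% solve(v[int_idx, int_idx, drop = FALSE]) %*% b[int_idx])
  structure(
    list(
      model = model, slopes = slopes,
      interaction = tibble(
        statistic = wald, df = length(int_idx),
        p_value = pchisq(wald, length(int_idx), lower.tail = FALSE)
      ),
      n_obs = nrow(dat)
    ),
    class = "threshold_regression"
  )
}

#' @export
print.threshold_regression <- function(x, ...) {
  cat("<threshold_regression> slope of group-difference t on cutoff, by node class\n")
  print(x$slopes)
  cat(sprintf(
    "cutoff x node-class interaction: Wald chi-square(%d) = %.2f, p = %.3g\n",
    x$interaction$df, x$interaction$statistic, x$interaction$p_value
  ))
  invisible(x)
}

#' @export
tidy.threshold_regression <- function(x, ...) x$slopes

#' @export
glance.threshold_regression <- function(x, ...) {
  tibble(
    interaction_chisq = x$interaction$statistic,
    interaction_df = x$interaction$df,
    interaction_p = x$interaction$p_value,
    n_obs = x$n_obs
  )
}

#' Multilevel regression of z-scored module degree on group
#'
#' Fits `z ~ module + module:group + density + (1 | replication)` on node-level
#' observations and extracts, per module, the patient-group coefficient: the
#' expected difference (patient minus control) in z-scored within- or
#' between-module degree, adjusted for density, with replication samples as
#' random intercepts.
#'
#' @param data A tibble with columns `z`, `module`, `group`, `density`, and
#'   `replication`.
#' @return A `module_regression` object; [tidy()] returns one row per module
#'   with `estimate` (patient minus control, z units), `se`, `t_value`, and a
#'   Wald 95% CI.
#' @export
module_group_regression <- function(data) {
  needed <- c("z", "module", "group", "density", "replication")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  dat <- data %>%
    filter(!is.na(.data$z)) %>%
    mutate(
      module = droplevels(factor(.data$module)),
      group = factor(.data$group, levels = c("control", "patient")),
      replication = factor(.data$replication)
    )
  model <- lme4::lmer(z ~ module + module:group + density + (1 | replication),
                      data = dat, REML = TRUE)
  b <- lme4::fixef(model)
  v <- as.matrix(stats::vcov(model))
  mods <- levels(dat$module)
  effects <- purrr::map_dfr(mods, function(m) {
    nm <- paste0("module", m, ":grouppatient")
    est <- b[[nm]]
    se <- sqrt(v[nm, nm])
    tibble(
      module = m, estimate = est, se = se, t_value = est / se,
      conf_low = est - 1.96 * se, conf_high = est + 1.96 * se
    )
  })
  structure(
    list(model = model, effects = effects, n_obs = nrow(dat)),
    class = "module_regression"
  )
}

#' @export
print.module_regression <- function(x, ...) {
  cat("<module_regression> patient-minus-control effect on z-scored module degree\n")
  print(x$effects)
  invisible(x)
}

#' @export
tidy.module_regression <- function(x, ...) x$effects

#' @export
glance.module_regression <- function(x, ...) {
  tibble(n_obs = x$n_obs, sigma = stats::sigma(x$model))
}
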