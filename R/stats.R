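# Group-difference inference. Metric tables follow a fixed tidy schema:
# one row per observation with columns `node`, `subject`, `group` (patient /
# control), `value`, plus any grouping keys (`cutoff`, `replication`,
# `strategy`, `density`, ...). All effects are patient minus control.

# vectorized two-sample t from group summaries; Welch and pooled give the
# same t for equal group sizes but different df
two_sample_t <- function(mp, mc, vp, vc, np, nc, var_method = "welch") {
  if (var_method == "pooled") {
    sp2 <- ((np - 1) * vp + (nc - 1) * vc) / (np + nc - 2)
    se <- sqrt(sp2 * (1 / np + 1 / nc))
    df <- rep.int(np + nc - 2, length(mp))
  } else {
    se <- sqrt(vp / np + vc / nc)
    df <- (vp / np + vc / nc)^2 /
      ((vp / np)^2 / (np - 1) + (vc / nc)^2 / (nc - 1))
  }
  zero_var <- is.na(se) | se == 0
  t_stat <- ifelse(zero_var, 0, (mp - mc) / se)
  p <- ifelse(zero_var, 1, 2 * pt(-abs(t_stat), df))
  list(t = t_stat, df = ifelse(zero_var, np + nc - 2, df), p = p,
       zero_variance = zero_var)
}

# fast path on a nodes x subjects value matrix
group_t_matrix <- function(values, is_patient, var_method = "welch") {
  np <- sum(is_patient); nc <- sum(!is_patient)
  xp <- values[, is_patient, drop = FALSE]
  xc <- values[, !is_patient, drop = FALSE]
  mp <- rowMeans(xp); mc <- rowMeans(xc)
  vp <- (rowSums(xp^2) - np * mp^2) / (np - 1)
  vc <- (rowSums(xc^2) - nc * mc^2) / (nc - 1)
  vp <- pmax(vp, 0); vc <- pmax(vc, 0)
  two_sample_t(mp, mc, vp, vc, np, nc, var_method)
}

#' Nodewise two-sample t tests (patient minus control)
#'
#' Runs an independent-samples t test per node within every combination of
#' grouping keys present in the table. Rows with zero variance in both groups
#' are returned with `t = 0`, `p = 1` and flagged rather than dropped.
#'
#' @param data A tidy metric table with columns `node`, `group`, `value`, and
#'   optionally further keys (`cutoff`, `replication`, ...).
#' @param var_method `"welch"` (default) or `"pooled"` variance.
#' @return A tibble with one row per (keys, node): `t`, `df`, `p`,
#'   `zero_variance`, plus group means.
#' @export
nodewise_t_tests <- function(data, var_method = c("welch", "pooled")) {
  var_method <- match.arg(var_method)
  needed <- c("node", "group", "value")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  keys <- setdiff(names(data), c("group", "value", "subject"))
  out <- data %>%
    as_tibble() %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      n_p = sum(.data$group == "patient"),
      n_c = sum(.data$group == "control"),
      mean_patient = mean(.data$value[.data$group == "patient"]),
      mean_control = mean(.data$value[.data$group == "control"]),
      var_p = var(.data$value[.data$group == "patient"]),
      var_c = var(.data$value[.data$group == "control"]),
      .groups = "drop"
    )
  if (any(out$n_p < 2 | out$n_c < 2)) {
    stop_validation("both groups need >= 2 observations in every cell")
  }
  res <- two_sample_t(out$mean_patient, out$mean_control, out$var_p, out$var_c,
                      out$n_p, out$n_c, var_method)
  out %>%
    mutate(t = res$t, df = res$df, p = res$p, zero_variance = res$zero_variance) %>%
    select(-"var_p", -"var_c", -"n_p", -"n_c")
}

# multiresponse OLS of Y (subjects x nodes) on X; returns the t of column
# `which_coef`. The closed-form path the experiments use; lm() is its oracle.
multiresponse_coef_t <- function(x, y, which_coef) {
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) return(NULL)
  coefs <- qr.coef(qr_x, y)
  res <- y - x %*% coefs
  df <- nrow(x) - ncol(x)
  sigma2 <- colSums(res^2) / df
  # an exactly-fitted response has only rounding error left: treat as zero
  sigma2[sigma2 < 1e-12 * pmax(colMeans(y^2), 1e-300)] <- 0
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- unname(sqrt(sigma2 * xtx_inv[which_coef, which_coef]))
  b <- unname(coefs[which_coef, ])
  t_stat <- ifelse(se == 0, 0, b / se)
  list(t = t_stat, df = df, p = ifelse(se == 0, 1, 2 * pt(-abs(t_stat), df)),
       coef = b)
}

#' Group test with per-subject graph density as covariate
#'
#' For each node (within every combination of the remaining keys), fits a
#' linear model of the metric on group plus the subject's realized graph
#' density and returns the group-coefficient t statistic (patient minus
#' control). Intended for absolute-threshold graphs, where density varies
#' across subjects; when density is constant within a cell (as under
#' proportional thresholding) the covariate is dropped with a collinearity
#' warning and the plain two-group t is returned.
#'
#' @param data A tidy metric table with columns `node`, `subject`, `group`,
#'   `density`, `value`, and optional keys.
#' @return A tibble with one row per (keys, node): `t`, `df`, `p`, and
#'   `density_dropped`.
#' @export
covaried_group_test <- function(data) {
  needed <- c("node", "subject", "group", "density", "value")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  keys <- setdiff(names(data), c(needed))
  data <- as_tibble(data)
  cells <- if (length(keys) > 0) {
    split(data, data[keys], drop = TRUE)
  } else {
    list(data)
  }
  out <- purrr::map_dfr(cells, function(cell) {
    wide <- tidyr::pivot_wider(cell, id_cols = c("subject", "group", "density"),
                               names_from = "node", values_from = "value")
    nodes <- as.integer(setdiff(names(wide), c("subject", "group", "density")))
    y <- as.matrix(wide[, as.character(nodes)])
    g <- as.numeric(wide$group == "patient")
    d <- wide$density
    dropped <- is.na(sd(d)) || sd(d) == 0
    fit <- if (dropped) NULL else multiresponse_coef_t(cbind(1, g, d), y, 2L)
    if (is.null(fit)) {
      dropped <- TRUE
      fit <- multiresponse_coef_t(cbind(1, g), y, 2L)
    }
    base <- cell[match(nodes, cell$node), keys, drop = FALSE]
    tibble(base, node = nodes, t = fit$t, df = fit$df, p = fit$p,
           density_dropped = dropped)
  })
  if (any(out$density_dropped)) {
    warn("density constant within some cells; covariate dropped there (collinearity)")
  }
  arrange(out, across(all_of(c(keys, "node"))))
}

#' Aggregate nodewise results across replication samples
#'
#' Pools the nodes of each class within replications and summarizes the t and
#' p statistics across replications: mean and SD of t, mean p, and the
#' 10th/50th/90th percentiles of t.
#'
#' @param results A tibble with columns `node_class`, `t`, `p`, plus optional
#'   `strategy` and `cutoff`.
#' @param per_cutoff Keep `cutoff` as an aggregation key (`TRUE`) or average
#'   over it (`FALSE`).
#' @return An `aggregate_summary` tibble.
#' @export
aggregate_replications <- function(results, per_cutoff = FALSE) {
  if (!all(c("node_class", "t", "p") %in% names(results))) {
    stop_validation("results must have node_class, t, and p columns")
  }
  if (nrow(results) > 0 && "replication" %in% names(results) &&
      dplyr::n_distinct(results$replication) < 2) {
    warn("fewer than 2 replications; SDs and percentiles are degenerate")
  }
  keys <- intersect(c("strategy", "node_class", if (per_cutoff) "cutoff"), names(results))
  out <- results %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      mean_t = mean(.data$t), sd_t = sd(.data$t), mean_p = mean(.data$p),
      t_p10 = stats::quantile(.data$t, 0.10, names = FALSE),
      t_p50 = stats::quantile(.data$t, 0.50, names = FALSE),
      t_p90 = stats::quantile(.data$t, 0.90, names = FALSE),
      n = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("aggregate_summary", class(out))
  out
}
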