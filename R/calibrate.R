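#' Calibrate the weak negative shift against a mean-p anchor
#'
#' The whack-a-node experiment requires the Negative nodes' hypoconnectivity
#' to be *nonsignificant on average* in the weighted (strength-centrality)
#' analysis. This routine searches the magnitude of the negative shift by
#' bisection: each candidate magnitude is evaluated on a reduced set of
#' replication samples (with common random numbers across candidates, so the
#' objective is smooth and monotone), the weighted-strength two-sample test is
#' run at the Negative nodes, and the p values are averaged across nodes and
#' replications. The search stops when the replication-averaged p is within
#' `tolerance` of `target_mean_p`.
#'
#' @param groundtruth A `ground_truth` object.
#' @param target_mean_p Target replication-averaged p value in (0, 1).
#' @param tolerance Acceptable |mean p - target|.
#' @param max_iter Maximum bisection iterations.
#' @param n_replications Replication samples per candidate evaluation.
#' @param search_range Magnitude bracket (non-negative; the returned shift is
#'   the negated magnitude).
#' @param shift_positive,n_each,sigma_a,sigma_v,noise,n_patients,n_controls
#'   Whack-a-node design settings; see [make_whack_design()].
#' @param var_method Two-sample variance treatment; see [nodewise_t_tests()].
#' @param seed Master seed for the evaluation substreams.
#' @return A `shift_calibration` list: `shift` (negative, in correlation
#'   units), `achieved_mean_p`, `sd_p` (SD of the per-replication mean p),
#'   `n_iter`, and `trace` (one row per evaluated candidate).
#' @export
calibrate_negative_shift <- function(groundtruth, target_mean_p = 0.19,
                                     tolerance = 0.01, max_iter = 25,
                                     n_replications = 15,
                                     search_range = c(0, 0.12),
                                     shift_positive = 0.14, n_each = 3,
                                     sigma_a = NULL, sigma_v = NULL,
                                     noise = noise_params(),
                                     n_patients = 50, n_controls = 50,
                                     var_method = "welch", seed = 1) {
  if (target_mean_p <= 0 || target_mean_p >= 1) {
    stop_config("target_mean_p must be in (0, 1)")
  }
  if (search_range[1] < 0 || search_range[2] <= search_range[1]) {
    stop_config("search_range must be an increasing non-negative bracket")
  }

  evaluate <- function(magnitude) {
    p_by_rep <- vapply(seq_len(n_replications), function(r) {
      design <- make_whack_design(
        groundtruth, shift_positive = shift_positive,
        shift_negative = -magnitude, n_each = n_each,
        sigma_a = sigma_a, sigma_v = sigma_v, noise = noise,
        n_patients = n_patients, n_controls = n_controls,
        n_replications = 1, seed = substream_seed(seed, 61L, r)
      )
      ctx <- sim_context(groundtruth, design)
      cohort <- sim_cohort_ut(ctx, design, replication_id = r)
      strengths <- node_strengths_ut(ctx, pmax(cohort$values, 0))
      res <- group_t_matrix(
        strengths[design$node_classes$Negative, , drop = FALSE],
        cohort$group == "patient", var_method
      )
      mean(res$p)
    }, numeric(1))
    list(mean_p = mean(p_by_rep), sd_p = sd(p_by_rep))
  }

  trace <- tibble(iteration = integer(), magnitude = numeric(), mean_p = numeric())
  lo <- search_range[1]; hi <- search_range[2]
  e_lo <- evaluate(lo); e_hi <- evaluate(hi)
  trace <- bind_rows(trace,
                     tibble(iteration = 0L, magnitude = lo, mean_p = e_lo$mean_p),
                     tibble(iteration = 0L, magnitude = hi, mean_p = e_hi$mean_p))
  if (e_lo$mean_p < target_mean_p - tolerance || e_hi$mean_p > target_mean_p + tolerance) {
    abort(paste0(
      "calibration failed: search range does not bracket the target mean p\n",
      paste(utils::capture.output(print(trace)), collapse = "\n")
    ), class = "whackanode_calibration_error")
  }

  best <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    e_mid <- evaluate(mid)
    trace <- bind_rows(trace, tibble(iteration = it, magnitude = mid,
                                     mean_p = e_mid$mean_p))
    if (is.null(best) || abs(e_mid$mean_p - target_mean_p) <
        abs(best$mean_p - target_mean_p)) {
      best <- list(magnitude = mid, mean_p = e_mid$mean_p, sd_p = e_mid$sd_p,
                   iter = it)
    }
    if (abs(e_mid$mean_p - target_mean_p) <= tolerance) {
      return(structure(
        list(shift = -mid, achieved_mean_p = e_mid$mean_p, sd_p = e_mid$sd_p,
             target_mean_p = target_mean_p, tolerance = tolerance,
             n_iter = it, n_replications = n_replications, trace = trace,
             seed = seed),
        class = "shift_calibration"
      ))
    }
    if (e_mid$mean_p > target_mean_p) lo <- mid else hi <- mid
  }
  abort(paste0(
    sprintf(
      "calibration did not reach |mean p - %.3f| <= %.4g within %d iterations\n",
      target_mean_p, tolerance, max_iter
    ),
    paste(utils::capture.output(print(trace)), collapse = "\n")
  ), class = "whackanode_calibration_error")
}

#' @export
print.shift_calibration <- function(x, ...) {
  cat(sprintf(
    "<shift_calibration> shift = %.4f (mean p = %.3f, SD %.3f; target %.3f, %d iterations)\n",
    x$shift, x$achieved_mean_p, x$sd_p, x$target_mean_p, x$n_iter
  ))
  invisible(x)
}

# node strengths (nodes x subjects) from an upper-tri value matrix
node_strengths_ut <- function(ctx, values_ut) {
  inc <- Matrix::sparseMatrix(
    i = c(ctx$pairs[, "i"], ctx$pairs[, "j"]),
    j = rep.int(seq_len(nrow(ctx$pairs)), 2L),
    x = 1,
    dims = c(ctx$n, nrow(ctx$pairs))
  )
  as.matrix(inc %*% values_ut)
}
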