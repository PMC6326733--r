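whack_smoke <- function(seed = 1, ...) {
  gt <- small_gt(seed = 3)
  run_whack_a_node(
    gt, n_replications = 2, densities = c(0.10, 0.20),
    r_cutoffs = c(0.2, 0.3), n_each = 2,
    n_patients = 6, n_controls = 6, seed = seed, ...
  )
}

test_that("the whack-a-node driver emits schema-stable, deterministic tables", {
  res <- whack_smoke(seed = 1)
  expect_s3_class(res, "whack_result")
  expect_setequal(
    names(res$results),
    c("replication", "strategy", "cutoff", "node", "node_class", "t", "df", "p")
  )
  expect_setequal(unique(res$results$strategy),
                  c("pt", "absolute", "absolute_density", "weighted"))
  expect_setequal(unique(res$results$node_class),
                  c("Positive", "Negative", "Comparator"))
  # 2 reps x (2 + 2 + 2 cutoffs + 1 weighted) x 6 tracked nodes
  expect_equal(nrow(res$results), 2 * 7 * 6)
  expect_true(all(res$results$p > 0 & res$results$p <= 1))

  res2 <- whack_smoke(seed = 1)
  expect_identical(res$results, res2$results)
  res3 <- whack_smoke(seed = 2)
  expect_false(identical(res$results$t, res3$results$t))

  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_replications, 2)
})

test_that("a null design produces no systematic group differences", {
  gt <- small_gt(seed = 6, n = 60, k = 5)
  res <- run_whack_a_node(
    gt, n_replications = 4, densities = c(0.10, 0.20),
    r_cutoffs = c(0.2, 0.3), shift_positive = 0, shift_negative = 0,
    n_each = 3, n_patients = 20, n_controls = 20, seed = 4
  )
  agg <- res$aggregate
  expect_true(all(abs(agg$mean_t) < 1))
  expect_true(all(agg$mean_p > 0.2))
})

test_that("flipping the shifts reverses the sign of the detected effects", {
  gt <- small_gt(seed = 3, n = 60, k = 5)
  res <- run_whack_a_node(
    gt, n_replications = 3, arms = "weighted", n_each = 3,
    n_patients = 20, n_controls = 20, flipped = TRUE, seed = 5
  )
  agg <- res$aggregate
  expect_lt(agg$mean_t[agg$node_class == "Positive"], -2)
  expect_gt(agg$mean_p[agg$node_class == "Negative"], 0.05)
})

test_that("proportional-mode shifts still produce the whack-a-node pattern", {
  gt <- small_gt(seed = 3, n = 60, k = 5)
  res <- run_whack_a_node(
    gt, n_replications = 3, arms = c("pt", "weighted"),
    densities = c(0.10, 0.15, 0.20), n_each = 3,
    n_patients = 20, n_controls = 20, proportional = TRUE, seed = 6
  )
  agg <- res$aggregate
  pt <- agg[agg$strategy == "pt", ]
  expect_gt(pt$mean_t[pt$node_class == "Positive"], 2)
  expect_lt(pt$mean_t[pt$node_class == "Negative"],
            pt$mean_t[pt$node_class == "Comparator"])
})

test_that("whack result bundles export as TSVs plus a manifest", {
  res <- whack_smoke(seed = 1)
  dir <- tempfile()
  write_whack_result(res, dir)
  expect_true(all(file.exists(file.path(
    dir, c("results.tsv", "aggregate.tsv", "aggregate_by_cutoff.tsv", "manifest.yaml")
  ))))
  back <- readr::read_tsv(file.path(dir, "results.tsv"), show_col_types = FALSE)
  expect_equal(nrow(back), nrow(res$results))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(manifest$seed, 1)
  expect_type(manifest$config_hash, "character")
})

test_that("the global driver computes sigma and module-degree tables", {
  gt <- generate_groundtruth(focal_partition(), seed = 2)
  res <- suppressWarnings(suppressMessages(run_global_insensitivity(
    gt, n_replications = 2, densities = c(0.10, 0.20), n_null = 3,
    report_densities = c(0.10, 0.20),
    design_args = list(n_patients = 6, n_controls = 6), seed = 7
  )))
  expect_s3_class(res, "global_result")
  expect_equal(nrow(res$sigma_results), 2 * 12 * 2)
  expect_true(all(res$sigma_results$sigma > 0))
  expect_setequal(unique(res$module_results$module),
                  c("DMN", "FPN", "DAN", "Visual"))
  expect_setequal(unique(res$module_summary$density), c(0.10, 0.20))
  expect_setequal(unique(res$module_summary$scope), c("within", "between"))
  # z decomposition: within + between degree equals total degree
  mr <- res$module_results
  expect_true(all(mr$within_degree + mr$between_degree >= 0))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(tidy(res)), 8)

  res2 <- suppressWarnings(suppressMessages(run_global_insensitivity(
    gt, n_replications = 2, densities = c(0.10, 0.20), n_null = 3,
    report_densities = c(0.10, 0.20),
    design_args = list(n_patients = 6, n_controls = 6), seed = 7
  )))
  expect_identical(res$sigma_results, res2$sigma_results)

  dir <- tempfile()
  write_global_result(res, dir)
  expect_true(file.exists(file.path(dir, "sigma_results.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
})

test_that("the global driver names missing module labels", {
  gt <- small_gt(seed = 1)  # partition without FPN/DAN/DMN labels
  expect_error(run_global_insensitivity(gt, n_replications = 2, seed = 1),
               "FPN", class = "whackanode_design_error")
})

test_that("calibration tracks the target mean p and fails when unattainable", {
  gt <- small_gt(seed = 5, n = 60, k = 5)
  # monotonicity: larger negative shifts push the weighted mean p down
  mean_p_at <- function(mag) {
    res <- run_whack_a_node(
      gt, n_replications = 3, arms = "weighted", shift_negative = -mag,
      n_each = 3, n_patients = 20, n_controls = 20, seed = 13
    )
    agg <- res$aggregate
    agg$mean_p[agg$node_class == "Negative"]
  }
  p0 <- mean_p_at(0)
  p1 <- mean_p_at(0.1)
  p2 <- mean_p_at(0.25)
  expect_gt(p0, p1)
  expect_gt(p1, p2)
  expect_gt(p0, 0.25)

  # bisection converges to the anchor inside the monotone range
  cal <- calibrate_negative_shift(
    gt, target_mean_p = 0.2, tolerance = 0.05, n_replications = 8,
    n_patients = 20, n_controls = 20, search_range = c(0, 0.3), seed = 17
  )
  expect_lt(cal$shift, 0)
  expect_lt(abs(cal$shift), 0.2)
  expect_lt(abs(cal$achieved_mean_p - 0.2), 0.0501)
  expect_s3_class(cal$trace, "tbl_df")

  expect_error(
    calibrate_negative_shift(
      gt, target_mean_p = 0.3, tolerance = 0, max_iter = 2,
      n_replications = 2, n_patients = 10, n_controls = 10,
      search_range = c(0, 0.3), seed = 17
    ),
    class = "whackanode_calibration_error"
  )
})

test_that("autoplot methods return ggplot objects", {
  res <- whack_smoke(seed = 1)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res, cutoffs = c(0.10, 0.20)), "ggplot")

  gt <- generate_groundtruth(focal_partition(), seed = 2)
  gres <- suppressMessages(run_global_insensitivity(
    gt, n_replications = 2, densities = c(0.10, 0.20), n_null = 2,
    design_args = list(n_patients = 5, n_controls = 5), seed = 3
  ))
  expect_s3_class(autoplot(gres, "sigma"), "ggplot")
  expect_s3_class(autoplot(gres, "modules"), "ggplot")
})
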