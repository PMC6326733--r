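quiet_noise <- noise_params(0, 0, 0)

test_that("with all variance sources at zero a subject equals the groundtruth", {
  gt <- small_gt(seed = 1)
  des <- experiment_design(5, 5, noise = quiet_noise, seed = 1)
  s <- simulate_subject(gt, des, "patient")
  expect_equal(s$values, unname(gt$values), ignore_attr = TRUE)
  expect_equal(s$b_s, 0)
})

test_that("sigma_b alone shifts every edge by the same person-level constant", {
  gt <- small_gt(seed = 1)
  des <- experiment_design(5, 5, noise = noise_params(0.2, 0, 0), seed = 2)
  set.seed(99)
  s <- simulate_subject(gt, des, "control")
  diffs <- (s$values - gt$values)[upper.tri(gt$values)]
  expect_equal(unname(diffs), rep(s$b_s, length(diffs)), tolerance = 1e-12)
  expect_false(s$b_s == 0)
})

test_that("targeted shifts apply once per edge, never compounding", {
  gt <- small_gt(seed = 1)
  manip <- node_manipulation(c(3, 7), mu_a = 0.14, sigma_a = 0, sigma_v = 0,
                             group = "patient")
  des <- experiment_design(5, 5, noise = quiet_noise,
                           manipulations = list(manip), seed = 3)
  s <- simulate_subject(gt, des, "patient")
  delta <- s$values - gt$values
  # the edge between the two targets is shifted once: 0.14, not 0.28
  expect_equal(delta[3, 7], 0.14, tolerance = 1e-12)
  expect_equal(delta[3, 12], 0.14, tolerance = 1e-12)
  expect_equal(delta[7, 20], 0.14, tolerance = 1e-12)
  expect_equal(delta[10, 20], 0, tolerance = 1e-12)
  # controls are untouched
  c0 <- simulate_subject(gt, des, "control")
  expect_equal(c0$values, unname(gt$values), ignore_attr = TRUE)
})

test_that("empirical moments match the multilevel model", {
  gt <- small_gt(seed = 2, n = 20, k = 2)
  manip <- node_manipulation(1L, mu_a = 0.1, sigma_a = 0.03, sigma_v = 0.04,
                             group = "patient")
  des <- experiment_design(5, 5, noise = noise_params(0.08, 0.05, 0.05),
                           manipulations = list(manip), seed = 11)
  ctx <- whackanode:::sim_context(gt, des)
  set.seed(42)
  n_mc <- 800
  targeted <- matrix(0, n_mc, 1)   # edge (1, 5): incident to the target
  plain <- matrix(0, n_mc, 1)      # edge (10, 15): untargeted
  for (i in seq_len(n_mc)) {
    d <- whackanode:::sim_subject_values(ctx, des, "patient")
    m <- whackanode:::ut_to_matrix(d$values_ut, 20)
    targeted[i] <- m[1, 5]
    plain[i] <- m[10, 15]
  }
  se_t <- sd(targeted) / sqrt(n_mc)
  expect_lt(abs(mean(targeted) - (gt$values[1, 5] + 0.1)), 3 * se_t)
  se_p <- sd(plain) / sqrt(n_mc)
  expect_lt(abs(mean(plain) - gt$values[10, 15]), 3 * se_p)
  # variance decomposition at an untargeted edge: sigma_b^2 + sigma_w^2 + sigma_e^2
  expect_equal(var(plain[, 1]), 0.08^2 + 0.05^2 + 0.05^2, tolerance = 0.15)
})

test_that("cohorts are deterministic per (seed, replication) and sized to design", {
  gt <- small_gt(seed = 1)
  des <- experiment_design(6, 4, noise = noise_params(), seed = 5)
  c1 <- simulate_cohort(gt, des, replication_id = 2)
  c2 <- simulate_cohort(gt, des, replication_id = 2)
  expect_identical(c1$subjects[[3]]$values, c2$subjects[[3]]$values)
  expect_equal(sum(vapply(c1$subjects, function(s) s$group == "patient", logical(1))), 6)
  expect_equal(sum(vapply(c1$subjects, function(s) s$group == "control", logical(1))), 4)

  c3 <- simulate_cohort(gt, des, replication_id = 3)
  expect_false(c1$subjects[[1]]$b_s == c3$subjects[[1]]$b_s)
})

test_that("proportional mode scales with groundtruth strength and spares zero edges", {
  w <- diag(10)
  w[upper.tri(w)] <- 0.3
  w <- w + t(w) - diag(10) * 0 ; diag(w) <- 1
  w[1, 2] <- w[2, 1] <- 0       # a zero-strength edge incident to the target
  w[1, 3] <- w[3, 1] <- 0.6     # a strong edge
  w[4, 5] <- w[5, 4] <- 0.7     # keeps mean within-module FC above between
  part <- generate_partition(10, module_sizes = c(5, 5))
  gt <- as_groundtruth(w, part)
  manip <- node_manipulation(1L, mu_a = 0.1, sigma_a = 0, sigma_v = 0,
                             group = "patient", mode = "proportional")
  des <- experiment_design(5, 5, noise = quiet_noise,
                           manipulations = list(manip), seed = 7)
  s <- simulate_subject(gt, des, "patient")
  delta <- s$values - w
  expect_equal(delta[1, 2], 0)
  expect_gt(delta[1, 3], 0)
  # shift is proportional to the groundtruth weight
  expect_equal(delta[1, 3] / w[1, 3], delta[1, 4] / w[1, 4], tolerance = 1e-12)
})

test_that("out-of-range values are clipped and counted", {
  w <- matrix(0.9, 6, 6); diag(w) <- 1
  w[1, 4] <- w[4, 1] <- 0.2  # keep within > between plausible
  part <- generate_partition(6, module_sizes = c(3, 3))
  gt <- as_groundtruth(w, part)
  manip <- node_manipulation(1L, mu_a = 0.5, sigma_a = 0, sigma_v = 0,
                             group = "patient")
  des <- experiment_design(5, 5, noise = quiet_noise,
                           manipulations = list(manip), seed = 1)
  s <- simulate_subject(gt, des, "patient")
  expect_true(all(abs(s$values[upper.tri(s$values)]) <= 0.999))
  expect_gt(s$n_clipped, 0)
})

test_that("designs validate overlap, SDs, and capacity", {
  gt <- small_gt(seed = 1)
  m1 <- node_manipulation(1:3, 0.1, group = "patient")
  m2 <- node_manipulation(3:5, -0.1, group = "patient")
  expect_error(experiment_design(5, 5, manipulations = list(m1, m2)),
               class = "whackanode_design_error")
  # same targets are fine in the other group or in disjoint edge scopes
  m3 <- node_manipulation(3:5, -0.1, group = "control")
  expect_silent(experiment_design(5, 5, manipulations = list(m1, m3)))
  m4 <- node_manipulation(1:3, 0.1, group = "patient", edge_scope = "within")
  m5 <- node_manipulation(1:3, 0.2, group = "patient", edge_scope = "between")
  expect_silent(experiment_design(5, 5, manipulations = list(m4, m5)))

  expect_error(node_manipulation(1:2, 0.1, sigma_a = -1),
               class = "whackanode_config_error")
  expect_error(experiment_design(1, 5), class = "whackanode_design_error")

  expect_silent(make_whack_design(gt, n_each = 13, seed = 1))
  expect_error(make_whack_design(gt, n_each = 14, seed = 1),
               class = "whackanode_design_error")
})

test_that("whack designs draw disjoint labeled sets; flipped reverses signs", {
  gt <- small_gt(seed = 1)
  des <- make_whack_design(gt, seed = 9)
  sets <- des$node_classes
  expect_named(sets, c("Positive", "Negative", "Comparator"))
  expect_equal(length(unique(unlist(sets))), 9)
  mus <- vapply(des$manipulations, function(m) m$mu_a, numeric(1))
  expect_equal(mus, c(0.14, -0.04))
  # SDs follow the half-mean coefficient of variation by default
  expect_equal(vapply(des$manipulations, function(m) m$sigma_a, numeric(1)),
               c(0.07, 0.02))

  flip <- make_whack_design(gt, flipped = TRUE, seed = 9)
  expect_equal(vapply(flip$manipulations, function(m) m$mu_a, numeric(1)),
               c(-0.14, 0.04))
  expect_identical(flip$node_classes, sets)
})

test_that("module designs target the stated systems with the stated scopes", {
  gt <- generate_groundtruth(focal_partition(), seed = 2)
  des <- make_module_design(gt, seed = 1)
  grp <- vapply(des$manipulations, function(m) m$group, character(1))
  scope <- vapply(des$manipulations, function(m) m$edge_scope, character(1))
  expect_equal(grp, c("control", "control", "patient", "patient"))
  expect_equal(scope, c("between", "within", "between", "within"))
  fd <- whackanode:::module_nodes(gt$partition, c("FPN", "DAN"))
  dmn <- whackanode:::module_nodes(gt$partition, "DMN")
  expect_setequal(des$manipulations[[1]]$target_nodes, fd)
  expect_setequal(des$manipulations[[3]]$target_nodes, dmn)

  expect_error(
    make_module_design(small_gt(), seed = 1),
    "FPN", class = "whackanode_design_error"
  )
})

test_that("degenerate-SD module design shifts exactly the stated edges", {
  gt <- generate_groundtruth(focal_partition(), seed = 2)
  des <- make_module_design(
    gt, between_sigma_a = 0, between_sigma_v = 0,
    within_sigma_a = 0, within_sigma_v = 0,
    noise = quiet_noise, seed = 1
  )
  ctrl <- simulate_subject(gt, des, "control")
  delta <- ctrl$values - gt$values
  part <- gt$partition
  fpn <- which(part$module == "FPN")
  dan <- which(part$module == "DAN")
  vis <- which(part$module == "Visual")
  other <- which(part$module == "Somatomotor")
  # between tier: FPN node to a foreign non-targeted module, exactly +0.2
  expect_equal(delta[fpn[1], other[1]], 0.2, tolerance = 1e-12)
  # within tier: FPN-FPN edge, exactly +0.1
  expect_equal(delta[fpn[1], fpn[2]], 0.1, tolerance = 1e-12)
  # FPN-DAN pairs are internal to the targeted system: within tier, +0.1
  expect_equal(delta[fpn[1], dan[1]], 0.1, tolerance = 1e-12)
  # the comparator module is untouched
  expect_equal(delta[vis[1], vis[2]], 0, tolerance = 1e-12)
  expect_equal(max(abs(delta[vis, vis])), 0, tolerance = 1e-12)

  pat <- simulate_subject(gt, des, "patient")
  dmn <- which(part$module == "DMN")
  dpat <- pat$values - gt$values
  expect_equal(dpat[dmn[1], other[1]], 0.2, tolerance = 1e-12)
  expect_equal(dpat[dmn[1], dmn[2]], 0.1, tolerance = 1e-12)
  expect_equal(max(abs(dpat[fpn, other])), 0, tolerance = 1e-12)
})

test_that("designs round-trip through YAML", {
  gt <- small_gt(seed = 1)
  des <- make_whack_design(gt, seed = 4, n_patients = 8, n_controls = 8)
  f <- tempfile(fileext = ".yaml")
  design_to_yaml(des, f)
  back <- design_from_yaml(f)
  expect_equal(back$n_patients, 8)
  expect_equal(back$noise, des$noise)
  expect_equal(lapply(back$manipulations, `[[`, "target_nodes"),
               lapply(des$manipulations, `[[`, "target_nodes"))
  expect_equal(back$node_classes$Positive, des$node_classes$Positive)
})

test_that("cohort export writes per-subject matrices plus a manifest", {
  gt <- small_gt(seed = 1)
  des <- experiment_design(3, 2, seed = 6)
  cohort <- simulate_cohort(gt, des, 1)
  dir <- tempfile()
  manifest <- write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_equal(nrow(manifest), 5)
  m <- as.matrix(utils::read.table(file.path(dir, manifest$file[1]), sep = "\t"))
  expect_equal(dim(m), c(40, 40))
})
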