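test_that("proportional thresholding retains an exact, density-determined edge count", {
  gt <- generate_groundtruth(generate_partition(), seed = 3)
  g <- binarize_proportional(gt, 0.25)
  m_all <- 264 * 263 / 2
  expect_equal(g$n_edges, round(0.25 * m_all))
  expect_equal(g$n_edges, 8679)
  expect_equal(g$mean_degree, 2 * 8679 / 264)
  expect_equal(g$mean_degree, g$density * 263, tolerance = 1e-12)

  all_pos <- matrix(0.5, 10, 10) + diag(0.5, 10)
  cg <- binarize_proportional(all_pos, 1.0)
  expect_equal(cg$n_edges, 45)
  expect_equal(cg$mean_degree, 9)
})

test_that("proportional ranking matches a brute-force sort on a toy matrix", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.10, 0.60, 0.25, 0.05, 0.45, 0.30)
  w <- w + t(w); diag(w) <- 1
  g <- binarize_proportional(w, 1 / 3)
  # 6 values, keep round(2) = top 2: 0.60 = (1,3) and 0.45 = (2,4)
  vals <- w[upper.tri(w)]
  expect_equal(g$n_edges, 2)
  expect_equal(g$adjacency[1, 3], 1)
  expect_equal(g$adjacency[2, 4], 1)
  expect_equal(sum(g$adjacency), 4)
})

test_that("proportional edge sets nest across densities", {
  set.seed(8)
  w <- whackanode:::ut_to_matrix(runif(45, -0.3, 0.9), 10)
  prev <- binarize_proportional(w, 0.05)$adjacency
  for (d in c(0.10, 0.15, 0.20, 0.25)) {
    cur <- binarize_proportional(w, d)$adjacency
    expect_true(all(cur[prev == 1] == 1))
    prev <- cur
  }
})

test_that("ties at the cutoff break by node-pair lexicographic order", {
  w <- matrix(0.5, 6, 6); diag(w) <- 1
  g <- binarize_proportional(w, 3 / 15)
  pairs <- whackanode:::upper_pairs(6)
  ord <- order(-rep(0.5, 15), pairs[, 1], pairs[, 2])
  expected <- pairs[ord[1:3], , drop = FALSE]
  expect_equal(sum(g$adjacency) / 2, 3)
  expect_true(all(g$adjacency[expected] == 1))
})

test_that("absolute thresholding nests, counts, and errors on empty graphs", {
  set.seed(9)
  w <- whackanode:::ut_to_matrix(runif(45, -0.3, 0.9), 10)
  hi <- binarize_absolute(w, 0.5)$adjacency
  lo <- binarize_absolute(w, 0.2)$adjacency
  expect_true(all(lo[hi == 1] == 1))

  toy <- whackanode:::ut_to_matrix(c(.1, .25, .3, .45, .6, .05), 4)
  expect_equal(binarize_absolute(toy, 0.2)$n_edges, 4)

  expect_error(binarize_absolute(toy, 0.9), "0\\.6",
               class = "whackanode_degenerate_graph")
  empty <- binarize_absolute(toy, 0.9, on_empty = "empty")
  expect_equal(empty$n_edges, 0)
  expect_error(binarize_proportional(toy, 1e-6),
               class = "whackanode_degenerate_graph")
})

test_that("negative-edge policies transform weights as stated", {
  w <- whackanode:::ut_to_matrix(c(0.2, -0.3, 0.5), 3)
  expect_equal(to_weighted(w, "discard")$adjacency[1, 3], 0)
  expect_equal(to_weighted(w, "abs")$adjacency[1, 3], 0.3)
  expect_equal(to_weighted(w, "retain")$adjacency[1, 3], -0.3)

  pos <- whackanode:::ut_to_matrix(c(0.2, 0.3, 0.5), 3)
  for (pol in c("discard", "abs", "retain")) {
    expect_equal(to_weighted(pos, pol)$adjacency[upper.tri(pos)],
                 c(0.2, 0.3, 0.5))
  }

  # node strengths by hand: edges (1,2)=.2, (1,3)=.3, (2,3)=.5
  g <- to_weighted(whackanode:::ut_to_matrix(c(0.2, 0.3, 0.5), 3), "retain")
  expect_equal(node_strength(g)$strength, c(0.5, 0.7, 0.8))
  # discard zeroes a negative edge out of both endpoints' strengths
  gn <- to_weighted(whackanode:::ut_to_matrix(c(0.2, -0.4, 0.5), 3), "discard")
  expect_equal(node_strength(gn)$strength, c(0.2, 0.7, 0.5))
})

test_that("density and mean degree satisfy their defining identities", {
  set.seed(10)
  w <- whackanode:::ut_to_matrix(runif(45, -0.2, 0.8), 10)
  for (d in c(0.1, 0.2, 0.5, 1.0)) {
    g <- binarize_proportional(w, d, negative_policy = "retain")
    s <- density_mean_degree(g)
    expect_equal(s$density, 2 * s$n_edges / (10 * 9), tolerance = 1e-15)
    expect_equal(s$mean_degree, s$density * 9, tolerance = 1e-15)
  }
  ring9 <- adj_from_edges(cbind(1:9, c(2:9, 10)), 10)
  g9 <- as_graph(ring9)
  s9 <- density_mean_degree(g9)
  expect_equal(s9$n_edges, 9)
  expect_equal(s9$density, 0.2)
  expect_equal(s9$mean_degree, 1.8)

  empty <- binarize_absolute(w, 0.99, on_empty = "empty")
  se <- density_mean_degree(empty)
  expect_equal(unlist(se), c(n_edges = 0, density = 0, mean_degree = 0))

  expect_error(density_mean_degree(to_weighted(w)), class = "whackanode_type_error")
})

test_that("proportional thresholding zero-sums group degree differences", {
  gt <- small_gt(seed = 5, n = 30, k = 3)
  des <- make_whack_design(gt, n_each = 2, n_patients = 6, n_controls = 6, seed = 2)
  cohort <- simulate_cohort(gt, des, 1)
  for (d in c(0.1, 0.2)) {
    degs <- vapply(cohort$subjects, function(s) {
      node_degree(binarize_proportional(s, d))$degree
    }, numeric(30))
    grp <- vapply(cohort$subjects, function(s) s$group, character(1))
    diff_sum <- sum(rowMeans(degs[, grp == "patient"]) -
                      rowMeans(degs[, grp == "control"]))
    expect_lt(abs(diff_sum), 1e-9)
  }
})

test_that("the vectorized threshold grid matches per-cutoff binarization", {
  set.seed(11)
  w <- whackanode:::ut_to_matrix(runif(190, -0.4, 0.9), 20)
  dens <- c(0.08, 0.15, 0.30)
  tab <- degree_by_threshold(w, "proportional", dens)
  for (d in dens) {
    ref <- node_degree(binarize_proportional(w, d))$degree
    expect_equal(tab$degree[tab$cutoff == d], ref)
  }
  cuts <- c(0.1, 0.3, 0.5)
  tab2 <- degree_by_threshold(w, "absolute", cuts)
  for (cc in cuts) {
    g <- binarize_absolute(w, cc)
    expect_equal(tab2$degree[tab2$cutoff == cc], node_degree(g)$degree)
    expect_equal(tab2$graph_density[tab2$cutoff == cc][1], g$density)
  }
})
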