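test_that("degree counts incident edges", {
  star <- adj_from_edges(cbind(1, 2:5), 5)
  expect_equal(node_degree(as_graph(star))$degree, c(4, 1, 1, 1, 1))

  set.seed(1)
  a <- random_graph(12)
  g <- as_graph(a)
  expect_equal(sum(node_degree(g)$degree), 2 * g$n_edges)
  expect_equal(node_degree(g)$degree, unname(oracle_degree(a)))
  expect_error(node_degree(to_weighted(a * 0.5)), class = "whackanode_type_error")
})

test_that("strength reduces to degree on binary graphs", {
  set.seed(2)
  a <- random_graph(10)
  expect_equal(node_strength(as_graph(a))$strength,
               node_degree(as_graph(a))$degree)
})

test_that("module degree decomposes the total by edge scope", {
  part <- generate_partition(6, module_sizes = c(3, 3))
  intra <- adj_from_edges(rbind(c(1, 2), c(2, 3), c(4, 5)), 6)
  g <- as_graph(intra)
  expect_equal(module_degree(g, part, "between")$degree, rep(0, 6))
  expect_equal(module_degree(g, part, "within")$degree,
               node_degree(g)$degree)

  set.seed(3)
  a <- random_graph(6, 0.6)
  gg <- as_graph(a)
  w <- module_degree(gg, part, "within")$degree
  b <- module_degree(gg, part, "between")$degree
  expect_equal(w + b, node_degree(gg)$degree)
  # brute-force per-edge classification
  mod <- rep(1:2, each = 3)
  w_ref <- vapply(1:6, function(i) sum(a[i, ] * (mod == mod[i])), numeric(1))
  expect_equal(w, w_ref)

  expect_error(module_degree(gg, generate_partition(8, n_modules = 2)),
               class = "whackanode_validation_error")
})

test_that("z-scoring standardizes within strata and flags degenerate ones", {
  tbl <- tibble::tibble(
    module = rep(c("A", "B"), each = 3),
    cutoff = 0.1,
    degree = c(2, 4, 6, 5, 5, 5)
  )
  expect_warning(out <- zscore_by_module_density(tbl), "zero-variance")
  expect_equal(out$z[1:3], c(-1, 0, 1))
  expect_true(all(is.na(out$z[4:6])))
  expect_true(all(out$zero_variance[4:6]))

  set.seed(4)
  big <- tibble::tibble(
    module = sample(c("A", "B", "C"), 300, TRUE),
    cutoff = sample(c(0.1, 0.2), 300, TRUE),
    degree = rnorm(300, 10, 3)
  )
  z <- zscore_by_module_density(big)
  chk <- dplyr::summarise(
    dplyr::group_by(z, module, cutoff),
    m = mean(z), s = sd(z), .groups = "drop"
  )
  expect_equal(chk$m, rep(0, nrow(chk)), tolerance = 1e-12)
  expect_equal(chk$s, rep(1, nrow(chk)), tolerance = 1e-12)
})

test_that("transitivity equals the triangle/triple ratio", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(graph_transitivity(as_graph(k4)), 1)

  p4 <- adj_from_edges(cbind(1:3, 2:4), 4)
  expect_equal(graph_transitivity(as_graph(p4)), 0)

  single <- adj_from_edges(cbind(1, 2), 3)
  expect_warning(ct <- graph_transitivity(as_graph(single)), "triples")
  expect_equal(ct, 0)

  set.seed(5)
  for (i in 1:10) {
    a <- random_graph(8, 0.45)
    expect_equal(graph_transitivity(as_graph(a)), oracle_transitivity(a))
  }
})

test_that("characteristic path length excludes and reports unreachable pairs", {
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(char_path_length(as_graph(k5))$path_length, 1)

  ring5 <- adj_from_edges(cbind(1:5, c(2:5, 1)), 5)
  r <- char_path_length(as_graph(ring5))
  expect_equal(r$path_length, 1.5)
  expect_equal(r$n_unreachable_pairs, 0)

  two_k3 <- adj_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3),
                                 c(4, 5), c(5, 6), c(4, 6)), 6)
  r2 <- char_path_length(as_graph(two_k3))
  expect_equal(r2$path_length, 1)
  expect_equal(r2$n_unreachable_pairs, 18)

  set.seed(6)
  for (i in 1:8) {
    a <- random_graph(8, 0.3)
    if (sum(a) == 0) next
    ref <- oracle_path_length(a)
    got <- char_path_length(as_graph(a))
    expect_equal(got$path_length, ref$path_length)
    expect_equal(got$n_unreachable_pairs, ref$n_unreachable)
  }
})

test_that("rewiring preserves the degree sequence exactly", {
  set.seed(7)
  a <- random_graph(20, 0.3)
  g <- as_graph(a)
  rg <- rewire_preserving_degree(g, seed = 1)
  expect_equal(node_degree(rg)$degree, node_degree(g)$degree)
  expect_equal(rg$n_edges, g$n_edges)
  expect_gt(attr(rg, "achieved_swaps"), 0)
  # rewiring actually moved edges
  expect_false(identical(rg$adjacency, g$adjacency))

  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  rk3 <- rewire_preserving_degree(as_graph(k3), seed = 1)
  expect_identical(rk3$adjacency, as_graph(k3)$adjacency)
  expect_equal(attr(rk3, "achieved_swaps"), 0)
})

test_that("the swap budget follows its two conventions", {
  expect_equal(swap_budget(n_nodes = 264, budget = "pairs"), 347160)
  expect_equal(swap_budget(n_edges = 123, budget = "edges"), 1230)
  expect_error(swap_budget(budget = "pairs"), class = "whackanode_config_error")
})

test_that("small-worldness is exactly 1 on complete graphs and label-invariant", {
  k20 <- matrix(1, 20, 20); diag(k20) <- 0
  sw <- small_worldness(as_graph(k20), n_null = 5, seed = 1)
  expect_equal(sw$sigma, 1)
  expect_equal(sw$component_coverage, 1)

  set.seed(8)
  a <- random_graph(60, 0.15)
  s1 <- small_worldness(as_graph(a), n_null = 20, seed = 2)$sigma
  perm <- sample(60)
  s2 <- small_worldness(as_graph(a[perm, perm]), n_null = 20, seed = 3)$sigma
  expect_lt(abs(s1 - s2), 0.15)
})

test_that("graph metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(9)
  for (i in 1:5) {
    a <- random_graph(30, 0.25)
    ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(graph_transitivity(as_graph(a)),
                 igraph::transitivity(ig, type = "global"))
    expect_equal(char_path_length(as_graph(a))$path_length,
                 igraph::mean_distance(ig, unconnected = TRUE))
    expect_equal(node_degree(as_graph(a))$degree, unname(igraph::degree(ig)))
  }
})
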