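two_triangles <- function() {
  igraph::make_graph(c(1,2, 2,3, 3,1, 4,5, 5,6, 6,4), directed = FALSE)
}

test_that("the pair graph collapses directed roles into typed pair edges", {
  duo <- fixture_two_mutualists()
  g <- community_graph(duo)
  expect_equal(igraph::ecount(g), 1)
  expect_identical(igraph::E(g)$type, "mutualism")

  # a consumer-resource pair yields one edge, not two
  chain <- fixture_three_chain()
  gc <- community_graph(chain)
  expect_equal(igraph::ecount(gc), 2)
  expect_true(all(igraph::E(gc)$type == "consumer_resource"))

  # non-interacting founders: edgeless graph with all nodes present
  founders <- community(x = rep(0.01, 5), r = 0.1, s = 1)
  gf <- community_graph(founders)
  expect_equal(igraph::vcount(gf), 5)
  expect_equal(igraph::ecount(gf), 0)
})

test_that("connectance counts realized unordered pairs", {
  expect_equal(connectance(igraph::make_full_graph(6)), 1)
  expect_equal(connectance(igraph::make_empty_graph(4, directed = FALSE)), 0)
  g <- igraph::sample_gnm(10, 9)
  expect_equal(connectance(g), 9 / 45)
  # single species: defined as zero
  expect_equal(connectance(community(x = 0.1, r = 0.1, s = 1)), 0)
})

test_that("degree entropy matches closed forms", {
  star <- igraph::make_star(4, mode = "undirected")
  expect_equal(degree_entropy(star),
               -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-12)
  # any k-regular graph (here a 6-cycle and the edgeless graph) has entropy 0
  expect_equal(degree_entropy(igraph::make_ring(6)), 0)
  expect_equal(degree_entropy(igraph::make_empty_graph(3,
                                                       directed = FALSE)), 0)
  # invariant under node relabeling
  set.seed(701)
  g <- igraph::sample_gnp(12, 0.3)
  perm <- sample(12)
  expect_equal(degree_entropy(igraph::permute(g, perm)), degree_entropy(g))
  expect_error(degree_entropy(igraph::make_empty_graph(0)), "empty")
})

test_that("Louvain modularity matches exhaustive search on small graphs", {
  g2t <- two_triangles()
  set.seed(702)
  expect_equal(graph_modularity(g2t), 0.5)
  expect_equal(exhaustive_modularity(g2t), 0.5)

  # the complete graph's single-community partition scores zero
  full <- igraph::make_full_graph(5)
  expect_equal(modularity_formula(full, rep(1, 5)), 0)

  # Louvain >= trivial partition, and == brute force for graphs up to 8 nodes
  set.seed(703)
  for (k in 1:8) {
    n <- sample(4:8, 1)
    g <- igraph::sample_gnp(n, 0.45)
    if (igraph::ecount(g) == 0) next
    triv <- modularity_formula(g, rep(1, n))
    louv <- graph_modularity(g)
    expect_gte(louv, triv)
    expect_equal(louv, exhaustive_modularity(g), tolerance = 1e-12)
  }
  expect_error(graph_modularity(igraph::make_empty_graph(3,
                                                         directed = FALSE)),
               "edgeless")
})

test_that("effective increase is centred on zero for Erdos-Renyi graphs", {
  set.seed(704)
  g <- igraph::sample_gnp(30, 0.25)
  # the observed graph IS an ER draw: increase ~ 0 within 3 baseline sds
  inc <- effective_increase(g, degree_entropy, n_random = 50)
  base <- replicate(50, degree_entropy(igraph::sample_gnp(30, connectance(g))))
  expect_lt(abs(inc), 3 * sd(base))
  # reproducible under a fixed seed
  set.seed(705)
  a <- effective_increase(two_triangles(), graph_modularity, n_random = 20)
  set.seed(705)
  b <- effective_increase(two_triangles(), graph_modularity, n_random = 20)
  expect_identical(a, b)
})

test_that("type proportions partition the realized pairs", {
  founders <- community(x = rep(0.01, 5), r = 0.1, s = 1)
  expect_equal(unname(type_proportions(founders)), c(0, 0, 0))

  sp <- data.frame(id = letters[1:4], r = 0.1, s = 1, x0 = 0.1)
  lk <- data.frame(from = c("a", "a", "c"), to = c("b", "c", "d"),
                   type = c("competition", "consumer_resource", "mutualism"),
                   w_ft = 0.1, w_tf = 0.15)
  co <- make_community(sp, lk)
  tp <- type_proportions(co)
  expect_equal(unname(tp), c(1, 1, 1) / 3)
  expect_equal(sum(tp), 1)
})

test_that("the metric report is internally consistent", {
  set.seed(706)
  co <- random_community(10, p_link = 0.4)
  rep <- community_metrics(co, baselines = TRUE, n_random = 20)
  expect_identical(nrow(rep), 1L)
  expect_equal(rep$SC, rep$S * rep$C)
  expect_gte(rep$C, 0); expect_lte(rep$C, 1)
  expect_equal(rep$prop_comp + rep$prop_cons + rep$prop_mut, 1)
})
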