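test_that("build_network thresholds with strict inequality", {
  store <- tiny_store()
  net <- build_network(store, 0.7)
  expect_equal(net$E, 1)
  expect_equal(net$p, 1 / 3)
  expect_equal(net$E_max, 3)

  # threshold 1 gives an empty graph (strict >)
  expect_equal(build_network(store, 1.0)$E, 0)
  # at the floor every stored pair is an edge
  expect_equal(build_network(store, 0.3)$E, 3)
  # below the floor the pairs were never computed
  expect_error(build_network(store, 0.2), "floor")
})

test_that("E(t) is non-increasing in t", {
  fix <- archetype_fixture()
  grid <- seq(0.3, 1, by = 0.05)
  e <- vapply(grid, function(t) build_network(fix$store, t)$E, 0)
  expect_true(all(diff(e) <= 0))
})

test_that("sample_er draws exactly e edges, uniformly", {
  # forced cases
  expect_equal(sample_er(5, 10, seed = 1)$E, 10)
  k5 <- sample_er(5, 10, seed = 2)
  expect_true(igraph::is_connected(k5$graph))
  expect_equal(sample_er(4, 0, seed = 1)$E, 0)
  expect_error(sample_er(4, 7, seed = 1), "e <=")

  # handshake identity and exact mean degree 2e/n
  for (seed in 1:5) {
    net <- sample_er(50, 120, seed = seed)
    degs <- igraph::degree(net$graph)
    expect_equal(sum(degs), 2 * 120)
    expect_equal(mean(degs), 2 * 120 / 50)
  }

  # reproducible under seed
  a <- sample_er(30, 60, seed = 99)
  b <- sample_er(30, 60, seed = 99)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
})

test_that("centralities match hand-enumerated small graphs", {
  # path A-B-C: betweenness (0, 1, 0)
  st <- similarity_store(3, floor = 0,
                         pairs = data.frame(i = c(1, 2), j = c(2, 3),
                                            similarity = c(0.9, 0.9)))
  prof <- centrality_profile(build_network(st, 0.5))
  expect_equal(prof$betweenness, c(0, 1, 0))
  expect_equal(prof$degree, c(1, 2, 1))

  # complete K4: eigenvector (0.5, 0.5, 0.5, 0.5) under unit L2 norm
  pairs <- as.data.frame(t(utils::combn(4, 2)))
  names(pairs) <- c("i", "j"); pairs$similarity <- 0.9
  k4 <- build_network(similarity_store(4, floor = 0, pairs = pairs), 0.5)
  prof4 <- centrality_profile(k4)
  expect_equal(prof4$eigenvector, rep(0.5, 4), tolerance = 1e-8)

  # star with 3 leaves: degrees (3,1,1,1), hub betweenness 3
  star <- similarity_store(4, floor = 0,
                           pairs = data.frame(i = c(1, 1, 1), j = 2:4,
                                              similarity = 0.9))
  profs <- centrality_profile(build_network(star, 0.5))
  expect_equal(profs$degree, c(3, 1, 1, 1))
  expect_equal(profs$betweenness, c(3, 0, 0, 0))
})

test_that("eigenvector centrality handles disconnected and empty graphs", {
  # two components: K3 and an edge; eigenvector lives on the K3
  st <- similarity_store(5, floor = 0,
                         pairs = data.frame(i = c(1, 1, 2, 4),
                                            j = c(2, 3, 3, 5),
                                            similarity = 0.9))
  prof <- centrality_profile(build_network(st, 0.5))
  expect_equal(prof$eigenvector[4:5], c(0, 0))
  expect_equal(sum(prof$eigenvector^2), 1, tolerance = 1e-10)
  expect_equal(prof$eigenvector[1:3], rep(1 / sqrt(3), 3),
               tolerance = 1e-8)

  # edgeless: all-equal eigenvector, zero degree/betweenness
  empty <- build_network(tiny_store(), 1.0)
  profe <- centrality_profile(empty)
  expect_equal(profe$eigenvector, rep(1 / sqrt(3), 3))
  expect_equal(profe$degree, c(0, 0, 0))
  expect_equal(profe$betweenness, c(0, 0, 0))
})

test_that("giant component fraction covers the degenerate cases", {
  # components 3 + 2 on 5 nodes
  st <- similarity_store(5, floor = 0,
                         pairs = data.frame(i = c(1, 1, 4), j = c(2, 3, 5),
                                            similarity = 0.9))
  expect_equal(giant_component_fraction(build_network(st, 0.5)), 3 / 5)
  # edgeless
  expect_equal(giant_component_fraction(build_network(st, 1.0)), 1 / 5)
  # connected
  k5p <- as.data.frame(t(utils::combn(5, 2)))
  names(k5p) <- c("i", "j"); k5p$similarity <- 0.9
  full <- build_network(similarity_store(5, floor = 0, pairs = k5p), 0.5)
  expect_equal(giant_component_fraction(full), 1)
})

test_that("assortativity matches hand-derived values and NA conventions", {
  path4 <- similarity_store(4, floor = 0,
                            pairs = data.frame(i = 1:3, j = 2:4,
                                               similarity = 0.9))
  expect_equal(assortativity_degree_safe(build_network(path4, 0.5)), -0.5)

  star <- similarity_store(4, floor = 0,
                           pairs = data.frame(i = c(1, 1, 1), j = 2:4,
                                              similarity = 0.9))
  expect_equal(assortativity_degree_safe(build_network(star, 0.5)), -1)

  # regular graph: zero degree variance => undefined, reported NA
  c5 <- similarity_store(5, floor = 0,
                         pairs = data.frame(i = c(1, 2, 3, 4, 1),
                                            j = c(2, 3, 4, 5, 5),
                                            similarity = 0.9))
  expect_true(is.na(assortativity_degree_safe(build_network(c5, 0.5))))
  # empty graph: undefined
  expect_true(is.na(assortativity_degree_safe(build_network(c5, 1.0))))
})

test_that("ER ensembles reproduce the giant-component closed form at c = 2", {
  # S solves S = 1 - exp(-c S); independent fixed-point oracle
  s_star <- 0.5
  for (k in 1:200) s_star <- 1 - exp(-2 * s_star)
  n <- 2000
  fracs <- vapply(1:20, function(r) {
    giant_component_fraction(sample_er(n, n, seed = derive_seed(11, r)))
  }, 0)
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - s_star), 3 * se + 1e-12)
})

test_that("large sparse ER graphs have assortativity near zero", {
  r <- vapply(1:20, function(k) {
    net <- sample_er(2000, round(0.01 * choose(2000, 2)),
                     seed = derive_seed(3, k))
    assortativity_degree_safe(net)
  }, 0)
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r)), 3 * se)
})

test_that("network export writes graphml, edges and centralities", {
  fix <- archetype_fixture()
  net <- build_network(fix$store, 0.5)
  prof <- centrality_profile(net)
  paths <- list(graphml = tempfile(fileext = ".graphml"),
                edges = tempfile(fileext = ".csv"),
                cent = tempfile(fileext = ".csv"))
  write_network(net, prof, paths$graphml, paths$edges, paths$cent)
  expect_true(file.exists(paths$graphml))
  back <- read.csv(paths$edges)
  expect_equal(nrow(back), net$E)
  cent <- read.csv(paths$cent)
  expect_equal(cent$degree, prof$degree)
})
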