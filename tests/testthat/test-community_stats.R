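make_clique_store <- function(k, size) {
  n <- k * size
  fam <- rep(seq_len(k), each = size)
  pairs <- t(utils::combn(n, 2))
  keep <- fam[pairs[, 1]] == fam[pairs[, 2]]
  similarity_store(
    n, floor = 0,
    pairs = data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                       similarity = 0.9)
  )
}

test_that("louvain recovers disjoint cliques with the closed-form modularity", {
  # k equal disconnected cliques: Q = 1 - 1/k
  net <- build_network(make_clique_store(2, 4), 0.5)
  part <- louvain_partition(net, seed = 1)
  expect_equal(part$n_communities, 2)
  expect_equal(part$sizes, c(4L, 4L))
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  expect_equal(part$fraction_connected, 1)

  net3 <- build_network(make_clique_store(3, 5), 0.5)
  part3 <- louvain_partition(net3, seed = 1)
  expect_equal(part3$modularity, 1 - 1 / 3, tolerance = 1e-12)
})

test_that("edgeless graphs give singleton communities", {
  net <- build_network(tiny_store(), 1.0)
  part <- louvain_partition(net, seed = 1)
  expect_equal(part$n_communities, 3)
  expect_equal(part$sizes, c(1L, 1L, 1L))
  expect_equal(part$fraction_connected, 0)
})

test_that("reported modularity matches the direct edge-list formula", {
  fix <- archetype_fixture()
  for (t in c(0.4, 0.6, 0.8)) {
    net <- build_network(fix$store, t)
    part <- louvain_partition(net, seed = 5)
    edges <- igraph::as_edgelist(net$graph, names = FALSE)
    expect_equal(part$modularity,
                 csntox:::modularity_direct(edges, part$assignment),
                 tolerance = 1e-10)
  }
})

test_that("descriptor_filter drops near-constant columns", {
  tab <- data.frame(
    constant = rep(1, 100),
    nearly = c(rep(0, 95), 1:5),          # 5% non-modal < 10%
    varied = rnorm(100),
    binary = rep(c(0, 1), 50)             # 50% non-modal
  )
  expect_message(out <- descriptor_filter(tab, 0.10), "dropped 2")
  expect_setequal(names(out), c("varied", "binary"))
  expect_setequal(attr(out, "dropped"), c("constant", "nearly"))
  expect_warning(descriptor_filter(data.frame(x = rep(1, 10)), 0.10),
                 "all descriptor columns dropped")
})

test_that("moods_median_test matches hand-computed tables", {
  res <- moods_median_test(list(c(1, 2, 3, 4), c(5, 6, 7, 8)))
  expect_equal(res$statistic, 8)
  expect_equal(res$p_value, pchisq(8, 1, lower.tail = FALSE))
  expect_equal(res$p_value, 0.004677735, tolerance = 1e-6)

  # identical samples: no signal
  same <- moods_median_test(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # balanced above/below counts: zero statistic
  bal <- moods_median_test(list(c(1, 3), c(2, 4)))
  expect_equal(bal$statistic, 0)

  # all values equal: degenerate table
  expect_error(moods_median_test(list(c(2, 2), c(2, 2))), "degenerate")
})

make_partition <- function(assignment) {
  sizes <- as.integer(sort(table(assignment), decreasing = TRUE))
  structure(list(assignment = assignment, sizes = sizes,
                 modularity = NA_real_, fraction_connected = NA_real_,
                 n_communities = length(sizes)),
            class = "community_partition")
}

test_that("the screen flags planted separations and not null descriptors", {
  set.seed(31)
  part <- make_partition(rep(1:3, each = 40))
  tab <- data.frame(
    separated = rep(c(10, 20, 30), each = 40) + rnorm(120),
    identical = rep(5, 120) + rnorm(120, sd = 0.5)
  )
  res <- community_descriptor_screen(tab, part, top_k = 3, alpha = 0.01)
  expect_true(res$significant[res$descriptor == "separated"])
  expect_false(res$significant[res$descriptor == "identical"])
  expect_equal(attr(res, "bonferroni_m"), 2 * 3)
  # medians reported per community regardless of the flag
  expect_equal(res$median_c1[1], 10, tolerance = 0.5)
  expect_equal(res$median_c3[1], 30, tolerance = 0.5)
})

test_that("the screen controls the type-I rate on null descriptors", {
  set.seed(97)
  part <- make_partition(rep(1:3, each = 40))
  null_tab <- as.data.frame(matrix(rnorm(120 * 200), nrow = 120))
  res <- community_descriptor_screen(null_tab, part, top_k = 3,
                                     alpha = 0.01)
  expect_lte(sum(res$significant), 0.01 * 200)
})

test_that("the screen is invariant to community relabelling", {
  set.seed(13)
  tab <- data.frame(a = rep(c(0, 3, 9), each = 30) + rnorm(90),
                    b = rnorm(90))
  p1 <- make_partition(rep(1:3, each = 30))
  perm <- c(2, 3, 1)
  p2 <- make_partition(perm[rep(1:3, each = 30)])
  r1 <- community_descriptor_screen(tab, p1, top_k = 3)
  r2 <- community_descriptor_screen(tab, p2, top_k = 3)
  expect_identical(r1$significant, r2$significant)
  expect_setequal(unname(round(unlist(r1[1, grep("median", names(r1))]), 6)),
                  unname(round(unlist(r2[1, grep("median", names(r2))]), 6)))
})

test_that("screen preconditions are enforced", {
  part <- make_partition(rep(1:2, each = 20))
  tab <- data.frame(x = rnorm(40))
  expect_error(community_descriptor_screen(tab, part, top_k = 3),
               "communities")
  small <- make_partition(c(rep(1, 30), rep(2, 6), rep(3, 4)))
  expect_error(community_descriptor_screen(data.frame(x = rnorm(40)),
                                           small, top_k = 3),
               ">= 5 members")
})
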