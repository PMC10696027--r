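two_family_store <- function(n1 = 20, n2 = 20, seed = 5) {
  st <- generate_planted_store(
    2, c(n1, n2), within_range = c(0.7, 0.9),
    between_range = c(0.31, 0.4), seed = seed,
    labels = c("toxic", "nontoxic")
  )
  st
}

test_that("neighbor vote is the similarity-weighted label average", {
  # node 3 has neighbours: toxic at s = 0.8, nontoxic at s = 0.7
  st <- similarity_store(
    3, labels = c("toxic", "nontoxic", "toxic"), floor = 0.3,
    pairs = data.frame(i = c(1, 2), j = c(3, 3),
                       similarity = c(0.8, 0.7))
  )
  net <- build_network(st, 0.5)
  train <- c("toxic", "nontoxic", NA)
  s <- neighbor_vote_score(3, net, train, st)
  expect_equal(s, 0.8 / 1.5, tolerance = 1e-12)
  expect_gte(s, 0.5)  # predicted toxic under the >= 0.5 rule

  # all neighbours toxic: score 1
  expect_equal(neighbor_vote_score(3, net, c("toxic", "toxic", NA), st), 1)
  # isolated node: unclassifiable
  empty_net <- build_network(st, 0.95)
  expect_true(is.na(neighbor_vote_score(3, empty_net, train, st)))
})

test_that("scores are convex combinations and monotone in duplicates", {
  set.seed(8)
  for (rep in 1:30) {
    k <- sample(2:6, 1)
    sims <- runif(k, 0.35, 0.95)
    labs <- sample(c("toxic", "nontoxic"), k, replace = TRUE)
    st <- similarity_store(
      k + 1, floor = 0.3,
      pairs = data.frame(i = seq_len(k), j = k + 1, similarity = sims)
    )
    net <- build_network(st, 0.3)
    train <- c(labs, NA)
    s <- neighbor_vote_score(k + 1, net, train, st)
    expect_gte(s, 0); expect_lte(s, 1)

    # adding a toxic neighbour never lowers the score
    st2 <- similarity_store(
      k + 2, floor = 0.3,
      pairs = data.frame(i = c(seq_len(k), k + 1), j = k + 2,
                         similarity = c(sims, 0.6))
    )
    net2 <- build_network(st2, 0.3)
    s2 <- neighbor_vote_score(k + 2, net2, c(labs, "toxic", NA), st2)
    expect_gte(s2 + 1e-12, s)
  }
})

test_that("equal weights reduce to an unweighted majority vote", {
  set.seed(17)
  for (rep in 1:50) {
    k <- sample(3:9, 1)
    labs <- sample(c("toxic", "nontoxic"), k, replace = TRUE)
    st <- similarity_store(
      k + 1, floor = 0.3,
      pairs = data.frame(i = seq_len(k), j = k + 1,
                         similarity = rep(0.6, k))
    )
    net <- build_network(st, 0.3)
    s <- neighbor_vote_score(k + 1, net, c(labs, NA), st)
    expect_equal(s, mean(labs == "toxic"), tolerance = 1e-12)
    expect_identical(s >= 0.5, mean(labs == "toxic") >= 0.5)
  }
})

test_that("classification metrics match the hand-worked confusion table", {
  y_true <- rep(c("toxic", "nontoxic"), c(10, 4))
  # TP = 9, FN = 1, TN = 1, FP = 3
  y_pred <- c(rep("toxic", 9), "nontoxic", "nontoxic", rep("toxic", 3))
  m <- classification_metrics(y_true, y_pred)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.25)
  expect_equal(m$accuracy, 10 / 14, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (9 / 12) * 0.9 / (9 / 12 + 0.9), tolerance = 1e-12)

  perfect <- classification_metrics(y_true, y_true)
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1, f1 = 1))

  # no negatives present: specificity undefined
  m2 <- classification_metrics(rep("toxic", 5), rep("toxic", 5))
  expect_true(is.na(m2$specificity))
  expect_error(classification_metrics(character(0), character(0)))
})

test_that("hold-out CV separates planted families and is reproducible", {
  st <- two_family_store()
  rep1 <- holdout_cv(st, t = 0.5, holdout = 0.8, iters = 30, seed = 19)
  expect_gte(rep1$mean[["accuracy"]], 0.95)
  expect_equal(rep1$n_unclassifiable, 0)

  # bitwise reproducible under the same seed
  rep2 <- holdout_cv(st, t = 0.5, holdout = 0.8, iters = 30, seed = 19)
  expect_identical(rep1$per_iteration, rep2$per_iteration)

  # single-class label sets are rejected
  st1 <- st; st1$labels <- rep("toxic", st$n_molecules)
  expect_error(holdout_cv(st1, t = 0.5, iters = 5, seed = 1),
               "both classes")
})

test_that("shuffled labels fall to the prevalence baseline", {
  st <- two_family_store(n1 = 30, n2 = 10)
  set.seed(4)
  shuffled <- sample(st$labels)
  rep <- holdout_cv(st, labels = shuffled, t = 0.5, holdout = 0.8,
                    iters = 100, seed = 23)
  prevalence <- mean(shuffled == "toxic")
  expect_lt(abs(rep$mean[["accuracy"]] - prevalence),
            3 * max(rep$sd[["accuracy"]], 0.02))
})

test_that("unclassifiable test nodes are imputed with the training majority", {
  # node 5 is isolated; majority of training labels is toxic
  st <- similarity_store(
    5, labels = c("toxic", "toxic", "toxic", "nontoxic", "toxic"),
    floor = 0.3,
    pairs = data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 3, 4),
                       similarity = c(0.9, 0.8, 0.85, 0.6))
  )
  rep <- holdout_cv(st, t = 0.35, holdout = 0.75, iters = 20, seed = 2)
  expect_gte(rep$n_unclassifiable, 0)
  expect_true(all(rep$per_iteration$accuracy >= 0,
                  rep$per_iteration$accuracy <= 1, na.rm = TRUE))
})
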