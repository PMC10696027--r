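# Similarity-weighted neighbour-vote toxicity classification.
#
# A node's score is the similarity-weighted average of its labelled
# training neighbours' labels (toxic = 1, nontoxic = 0) in the network
# thresholded at t, so the most similar chemicals dominate the vote.
# "toxic" is the positive class throughout.

#' Similarity-weighted neighbour vote score
#'
#' `score = sum_j s_nj * y_j / sum_j s_nj` over the node's network
#' neighbours `j` that carry a training label (`y = 1` toxic, `0`
#' nontoxic). A node with no labelled neighbour is unclassifiable and
#' returns `NA`.
#'
#' @param node node index (1-based) in the network.
#' @param net a `threshold_network` built from `store` at some cut-off.
#' @param train_labels character vector over all nodes: `"toxic"`,
#'   `"nontoxic"`, or `NA` for nodes outside the training set.
#' @param store the `similarity_store` the network was built from (source
#'   of the weights).
#' @return Score in `[0, 1]`, or `NA` if unclassifiable.
#' @export
neighbor_vote_score <- function(node, net, train_labels, store) {
  stopifnot(node >= 1, node <= net$n_nodes,
            length(train_labels) == net$n_nodes)
  nb <- as.integer(igraph::neighbors(net$graph, node))
  nb <- nb[!is.na(train_labels[nb]) &
             train_labels[nb] %in% c("toxic", "nontoxic")]
  if (length(nb) == 0) return(NA_real_)
  w <- pair_similarities(store, node, nb)
  y <- as.numeric(train_labels[nb] == "toxic")
  sum(w * y) / sum(w)
}

# look up stored similarities between `node` and each of `others`
pair_similarities <- function(store, node, others) {
  key <- ifelse(others < node,
                paste(others, node), paste(node, others))
  all_keys <- paste(store$pairs$i, store$pairs$j)
  store$pairs$similarity[match(key, all_keys)]
}

#' Binary classification metrics with toxic as positive class
#'
#' @param y_true,y_pred equal-length character vectors of `"toxic"` /
#'   `"nontoxic"`.
#' @return List `accuracy`, `sensitivity`, `specificity`, `f1`; ratios
#'   with a zero denominator are `NA`.
#' @examples
#' classification_metrics(rep(c("toxic", "nontoxic"), c(10, 4)),
#'                        rep(c("toxic", "nontoxic", "toxic"), c(9, 2, 3)))
#' @export
classification_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  tp <- sum(y_true == "toxic" & y_pred == "toxic")
  tn <- sum(y_true == "nontoxic" & y_pred == "nontoxic")
  fp <- sum(y_true == "nontoxic" & y_pred == "toxic")
  fn <- sum(y_true == "toxic" & y_pred == "nontoxic")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = ratio(tp + tn, length(y_true)),
       sensitivity = recall,
       specificity = ratio(tn, tn + fp),
       f1 = f1)
}

#' Repeated stratified hold-out cross-validation of the neighbour vote
#'
#' At threshold `t`, each iteration samples a stratified training set
#' (fraction `holdout` of each class, preserving the toxic/nontoxic
#' ratio — important because the nontoxic class is small), scores every
#' held-out node with [neighbor_vote_score()] using only training labels,
#' and predicts toxic iff `score >= 0.5` (ties go to toxic: the
#' application is hazard prioritisation, which favours sensitivity).
#' Unclassifiable (neighbour-less) test nodes are imputed with the
#' training majority class and counted. Metrics are aggregated over
#' iterations as mean and standard deviation. Bitwise reproducible for a
#' fixed seed.
#'
#' @param store a `similarity_store` with `labels` covering both classes
#'   (unlabelled molecules are ignored).
#' @param labels optional character labels overriding `store$labels`.
#' @param t similarity threshold at which the network is built.
#' @param holdout training fraction per class (default 0.8).
#' @param iters number of hold-out iterations (default 100).
#' @param seed master seed.
#' @return A `classification_report`: list with per-metric `mean` and
#'   `sd`, `n_unclassifiable` (mean per iteration), `threshold`,
#'   `n_iterations`, `holdout_fraction`, `seed`.
#' @export
holdout_cv <- function(store, labels = NULL, t, holdout = 0.8, iters = 100,
                       seed = 1) {
  labels <- labels %||% store$labels
  stopifnot(!is.null(labels), length(labels) == store$n_molecules,
            holdout > 0, holdout < 1, iters >= 1)
  labels[!labels %in% c("toxic", "nontoxic")] <- NA_character_
  idx_tox <- which(labels == "toxic")
  idx_non <- which(labels == "nontoxic")
  if (length(idx_tox) == 0 || length(idx_non) == 0) {
    stop("both classes must be present for cross-validation")
  }
  net <- build_network(store, t)
  metric_names <- c("accuracy", "sensitivity", "specificity", "f1")
  res <- matrix(NA_real_, iters, length(metric_names),
                dimnames = list(NULL, metric_names))
  unclass_n <- integer(iters)
  for (it in seq_len(iters)) {
    set.seed(derive_seed(seed, it))
    tr_tox <- sample(idx_tox, round(holdout * length(idx_tox)))
    tr_non <- sample(idx_non, round(holdout * length(idx_non)))
    train <- c(tr_tox, tr_non)
    test <- setdiff(c(idx_tox, idx_non), train)
    train_labels <- rep(NA_character_, store$n_molecules)
    train_labels[train] <- labels[train]
    majority <- if (length(tr_tox) >= length(tr_non)) "toxic" else "nontoxic"
    scores <- vapply(test, neighbor_vote_score, 0, net = net,
                     train_labels = train_labels, store = store)
    pred <- ifelse(is.na(scores), majority,
                   ifelse(scores >= 0.5, "toxic", "nontoxic"))
    unclass_n[it] <- sum(is.na(scores))
    mets <- classification_metrics(labels[test], pred)
    res[it, ] <- unlist(mets)
  }
  structure(
    list(mean = colMeans(res, na.rm = TRUE),
         sd = apply(res, 2, sd, na.rm = TRUE),
         per_iteration = as.data.frame(res),
         n_unclassifiable = mean(unclass_n),
         threshold = t, n_iterations = iters,
         holdout_fraction = holdout, seed = seed),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> t = ", x$threshold, ", ",
      x$n_iterations, " iterations (", x$holdout_fraction * 100,
      "% stratified hold-out)\n", sep = "")
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 4))
  cat("mean unclassifiable test nodes per iteration: ",
      x$n_unclassifiable, "\n", sep = "")
  invisible(x)
}

#' Classification performance across the threshold grid
#'
#' Runs [holdout_cv()] at every threshold of a grid and returns a tidy
#' data frame of metric means and sds per threshold.
#'
#' @inheritParams holdout_cv
#' @param grid ascending thresholds within `[floor, 1]`.
#' @return Data frame `threshold, metric, mean, sd, n_unclassifiable`.
#' @export
classification_sweep <- function(store, labels = NULL,
                                 grid = seq(0.30, 1.00, by = 0.01),
                                 holdout = 0.8, iters = 100, seed = 1) {
  rows <- lapply(seq_along(grid), function(k) {
    rep_k <- holdout_cv(store, labels, t = grid[k], holdout = holdout,
                        iters = iters, seed = derive_seed(seed, k))
    data.frame(threshold = grid[k], metric = names(rep_k$mean),
               mean = as.numeric(rep_k$mean), sd = as.numeric(rep_k$sd),
               n_unclassifiable = rep_k$n_unclassifiable)
  })
  do.call(rbind, rows)
}
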