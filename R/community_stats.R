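# Community structure at criticality and the descriptor screen.

#' Louvain community detection
#'
#' Runs Louvain modularity maximisation (resolution 1) on the unweighted
#' graph. Isolated nodes end up as singleton communities. The partition's
#' modularity and the fraction of non-isolated nodes are reported.
#' Louvain's greedy sweep order is randomised, so a seed is required for
#' reproducibility.
#'
#' @param net a `threshold_network`.
#' @param seed integer seed.
#' @return A `community_partition`: list with `assignment` (integer
#'   community id per node, ids ordered by decreasing size), `sizes`
#'   (descending), `modularity`, `fraction_connected`, `n_communities`.
#' @export
louvain_partition <- function(net, seed = 1) {
  stopifnot(net$n_nodes >= 1)
  set.seed(seed)
  if (net$E == 0) {
    assignment <- seq_len(net$n_nodes)
    q <- NA_real_
  } else {
    cl <- igraph::cluster_louvain(net$graph, resolution = 1)
    assignment <- as.integer(igraph::membership(cl))
    q <- igraph::modularity(net$graph, assignment)
  }
  # relabel communities by decreasing size (ties by first appearance)
  tab <- sort(table(assignment), decreasing = TRUE)
  relabel <- setNames(seq_along(tab), names(tab))
  assignment <- as.integer(relabel[as.character(assignment)])
  sizes <- as.integer(sort(table(assignment), decreasing = TRUE))
  structure(
    list(assignment = assignment, sizes = sizes, modularity = q,
         fraction_connected = mean(igraph::degree(net$graph) >= 1),
         n_communities = length(sizes)),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition> ", x$n_communities, " communities, Q = ",
      signif(x$modularity, 4), ", top sizes: ",
      paste(utils::head(x$sizes, 5), collapse = ", "),
      ", connected fraction = ", signif(x$fraction_connected, 3), "\n",
      sep = "")
  invisible(x)
}

# direct modularity formula from an edge list and an assignment, used as
# an independent cross-check of igraph's value
modularity_direct <- function(edges, assignment) {
  e_total <- nrow(edges)
  if (e_total == 0) return(NA_real_)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = length(assignment))
  q <- 0
  for (cc in unique(assignment)) {
    members <- which(assignment == cc)
    within <- sum(edges[, 1] %in% members & edges[, 2] %in% members)
    dc <- sum(deg[members])
    q <- q + within / e_total - (dc / (2 * e_total))^2
  }
  q
}

#' Drop near-constant molecular descriptors
#'
#' Removes every descriptor column whose variability — the fraction of
#' molecules *not* sharing the modal value — is below `min_variability`.
#' This catches constant and almost-constant columns regardless of scale
#' or sign (a coefficient-of-variation rule would not).
#'
#' @param table data frame of numeric descriptor columns (rows =
#'   molecules).
#' @param min_variability minimum fraction of non-modal values (default
#'   0.10).
#' @return The filtered data frame; dropped names are reported via
#'   `message()` and attached as `attr(, "dropped")`.
#' @export
descriptor_filter <- function(table, min_variability = 0.10) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  variability <- vapply(table, function(col) {
    tab <- table(col, useNA = "no")
    if (length(tab) == 0) return(0)
    1 - max(tab) / length(col[!is.na(col)])
  }, 0)
  drop <- names(table)[variability < min_variability]
  keep <- table[, variability >= min_variability, drop = FALSE]
  if (length(drop)) {
    message("descriptor_filter: dropped ", length(drop),
            " near-constant descriptor(s)")
  }
  if (ncol(keep) == 0) warning("all descriptor columns dropped")
  attr(keep, "dropped") <- drop
  keep
}

#' Mood's median test
#'
#' Nonparametric k-sample test of equal medians: counts values above vs
#' not-above the pooled grand median per group and applies the Pearson
#' chi-square test (k-1 degrees of freedom, no continuity correction).
#' Values equal to the grand median count as not-above.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @return List with `statistic` (chi-square), `p_value`, `df`,
#'   `grand_median`, and the 2 x k count `table`.
#' @examples
#' moods_median_test(list(c(1, 2, 3, 4), c(5, 6, 7, 8)))  # chisq = 8
#' @export
moods_median_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 0L) >= 1))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  pooled <- unlist(groups)
  gm <- median(pooled)
  above <- vapply(groups, function(g) sum(g > gm), 0)
  below <- vapply(groups, function(g) sum(g <= gm), 0)
  tab <- rbind(above = above, not_above = below)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("degenerate table in Mood's median test (zero expected cell)")
  }
  stat <- sum((tab - expected)^2 / expected)
  df <- length(groups) - 1
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE),
       df = df, grand_median = gm, table = tab)
}

#' Screen descriptors for separation among the top communities
#'
#' For the `top_k` most populated communities, each descriptor is tested
#' with all pairwise Mood's median tests (three tests for `top_k = 3`). A
#' descriptor is flagged significant only when *every* pairwise test
#' survives a Bonferroni correction with family size
#' `m = n_descriptors * choose(top_k, 2)` at level `alpha` — i.e. its
#' distribution is distinguishable among all top communities at once.
#' Per-community medians and interquartile ranges are reported for every
#' descriptor regardless of the flag.
#'
#' @param table data frame of numeric descriptors, rows aligned with the
#'   network nodes.
#' @param part a `community_partition` over the same nodes.
#' @param top_k number of communities screened (default 3); each must have
#'   at least 5 members.
#' @param alpha significance level (default 0.01).
#' @return A `screen_result`: data frame with raw pairwise p-values
#'   (`p_1_2`, ...), the `significant` flag, and `median_c<k>` /
#'   `iqr_c<k>` columns; attributes `alpha`, `bonferroni_m`, `top_k`,
#'   `community_sizes`.
#' @export
community_descriptor_screen <- function(table, part, top_k = 3,
                                        alpha = 0.01) {
  stopifnot(is.data.frame(table), nrow(table) == length(part$assignment))
  if (part$n_communities < top_k) {
    stop("need at least ", top_k, " communities, found ",
         part$n_communities)
  }
  comm_ids <- seq_len(top_k)  # assignment is size-ordered
  members <- lapply(comm_ids, function(cc) which(part$assignment == cc))
  sizes <- lengths(members)
  if (any(sizes < 5)) {
    stop("each of the top ", top_k, " communities needs >= 5 members")
  }
  pairs <- utils::combn(top_k, 2)
  m <- ncol(table) * ncol(pairs)
  rows <- lapply(names(table), function(d) {
    vals <- lapply(members, function(idx) table[[d]][idx])
    pv <- apply(pairs, 2, function(pr) {
      tryCatch(moods_median_test(vals[pr])$p_value,
               error = function(e) NA_real_)
    })
    adj <- pmin(1, pv * m)
    meds <- vapply(vals, median, 0, na.rm = TRUE)
    iqrs <- vapply(vals, function(v) diff(quantile(v, c(0.25, 0.75),
                                                   na.rm = TRUE,
                                                   names = FALSE)), 0)
    out <- data.frame(descriptor = d, stringsAsFactors = FALSE)
    for (k in seq_len(ncol(pairs))) {
      out[[paste0("p_", pairs[1, k], "_", pairs[2, k])]] <- pv[k]
    }
    out$significant <- all(!is.na(adj)) && all(adj < alpha)
    for (k in seq_len(top_k)) {
      out[[paste0("median_c", k)]] <- meds[k]
      out[[paste0("iqr_c", k)]] <- iqrs[k]
    }
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "alpha") <- alpha
  attr(res, "bonferroni_m") <- m
  attr(res, "top_k") <- top_k
  attr(res, "community_sizes") <- sizes
  class(res) <- c("screen_result", "data.frame")
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", nrow(x), " descriptors screened across top ",
      attr(x, "top_k"), " communities; ", sum(x$significant),
      " significant at alpha = ", attr(x, "alpha"),
      " (Bonferroni m = ", attr(x, "bonferroni_m"), ")\n", sep = "")
  invisible(x)
}

#' Write partition and screen artifacts
#'
#' @param part a `community_partition`.
#' @param ids node ids aligned with the assignment.
#' @param csv_path partition CSV (`node_id,community`).
#' @param json_path partition summary JSON.
#' @return `csv_path`, invisibly.
#' @export
write_partition <- function(part, ids, csv_path, json_path = NULL) {
  write.csv(data.frame(node_id = ids, community = part$assignment),
            csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(sizes = part$sizes, modularity = part$modularity,
           fraction_connected = part$fraction_connected),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(csv_path)
}
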