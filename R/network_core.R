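# Threshold networks, ER nulls and centrality metrics.
#
# Graphs are simple and undirected throughout; similarity weights are
# deliberately dropped after thresholding (the analysis is purely
# topological). All graph algorithms are igraph's.

#' Build the unweighted threshold network at a similarity cut-off
#'
#' Nodes are all molecules of the store; an edge joins `i` and `j` iff
#' their stored similarity is strictly greater than `t` (so `t = 1` always
#' yields an empty graph). Pairs below the store floor were never computed,
#' hence `t >= floor` is required.
#'
#' @param store a `similarity_store`.
#' @param t similarity cut-off, `floor <= t <= 1`.
#' @return A `threshold_network`: list with the igraph `graph`, `n_nodes`,
#'   `E` (edge count), `E_max = N(N-1)/2`, connection probability
#'   `p = E/E_max` and `threshold`.
#' @export
build_network <- function(store, t) {
  stopifnot(inherits(store, "similarity_store"))
  if (t < store$floor) {
    stop("threshold ", t, " is below the store floor ", store$floor,
         ": those pairs were never computed")
  }
  keep <- store$pairs$similarity > t
  n <- store$n_molecules
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- store$ids
  if (any(keep)) {
    g <- igraph::add_edges(
      g, rbind(store$pairs$i[keep], store$pairs$j[keep])
    )
  }
  threshold_network(g, threshold = t)
}

threshold_network <- function(graph, threshold = NA_real_) {
  n <- igraph::vcount(graph)
  e <- igraph::ecount(graph)
  emax <- n * (n - 1) / 2
  structure(
    list(graph = graph, n_nodes = n, E = e, E_max = emax,
         p = if (emax > 0) e / emax else NA_real_, threshold = threshold),
    class = "threshold_network"
  )
}

#' @export
print.threshold_network <- function(x, ...) {
  cat("<threshold_network> N = ", x$n_nodes, ", E = ", x$E,
      " (p = ", signif(x$p, 4), ")",
      if (!is.na(x$threshold)) paste0(", threshold = ", x$threshold) else "",
      "\n", sep = "")
  invisible(x)
}

#' Sample a uniform G(N, E) Erdos-Renyi graph
#'
#' Draws exactly `e` distinct edges uniformly without replacement among the
#' `n(n-1)/2` possible pairs — the null model with the same order and size
#' as a thresholded network, so degree parity with the observed network is
#' exact, not just in expectation.
#'
#' @param n number of nodes.
#' @param e number of edges, `0 <= e <= n(n-1)/2`.
#' @param seed integer seed for reproducibility.
#' @return A `threshold_network`.
#' @export
sample_er <- function(n, e, seed = NULL) {
  stopifnot(n >= 1, e >= 0, e <= n * (n - 1) / 2)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnm(n, e, directed = FALSE)
  threshold_network(g)
}

#' Degree, betweenness and eigenvector centrality profile
#'
#' Degree is the adjacency row sum; betweenness is the unnormalised
#' shortest-path pair ratio (each unordered pair counted once);
#' eigenvector centrality is the principal eigenvector of the adjacency
#' matrix computed by power iteration on the largest connected component
#' (zeros elsewhere), L2-normalised. An edgeless graph gets zero
#' degree/betweenness and the all-equal eigenvector by convention.
#'
#' @param net a `threshold_network`.
#' @param tol,max_iter power-iteration convergence controls.
#' @return A `centrality_profile`: list of per-node vectors `degree`,
#'   `betweenness`, `eigenvector` and their means.
#' @export
centrality_profile <- function(net, tol = 1e-10, max_iter = 10000) {
  g <- net$graph
  n <- igraph::vcount(g)
  stopifnot(n >= 1)
  deg <- as.numeric(igraph::degree(g))
  btw <- as.numeric(igraph::betweenness(g, directed = FALSE,
                                        normalized = FALSE))
  eig <- eigenvector_largest_component(g, tol = tol, max_iter = max_iter)
  structure(
    list(degree = deg, betweenness = btw, eigenvector = eig,
         mean_degree = mean(deg), mean_betweenness = mean(btw),
         mean_eigenvector = mean(eig)),
    class = "centrality_profile"
  )
}

# principal adjacency eigenvector on the largest component, zeros
# elsewhere, unit L2 norm; all-equal vector for edgeless graphs
eigenvector_largest_component <- function(g, tol = 1e-10, max_iter = 10000) {
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0) return(rep(1 / sqrt(n), n))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  members <- which(comp$membership == big)
  sub <- igraph::induced_subgraph(g, members)
  adj <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
  m <- length(members)
  v <- rep(1 / sqrt(m), m)
  for (it in seq_len(max_iter)) {
    w <- as.numeric(adj %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  out <- numeric(n)
  out[members] <- abs(v)
  out / sqrt(sum(out^2))
}

#' Fraction of nodes in the giant (largest) connected component
#'
#' @param net a `threshold_network`.
#' @return `max(component size) / N`, in `(0, 1]` (an edgeless graph of N
#'   nodes gives `1/N`).
#' @export
giant_component_fraction <- function(net) {
  stopifnot(net$n_nodes >= 1)
  comp <- igraph::components(net$graph)
  max(comp$csize) / net$n_nodes
}

#' Degree assortativity
#'
#' Pearson correlation of end-point degrees over the directed edge list
#' (each undirected edge contributes both orientations). Undefined when a
#' marginal degree variance is zero (e.g. regular graphs) or the graph has
#' no edges; such cases are reported as `NA`, never coerced to 0.
#'
#' @param net a `threshold_network`.
#' @return Assortativity coefficient in `[-1, 1]`, or `NA` when undefined.
#' @export
assortativity_degree_safe <- function(net) {
  if (net$E < 1) return(NA_real_)
  r <- suppressWarnings(igraph::assortativity_degree(net$graph,
                                                     directed = FALSE))
  if (is.nan(r)) NA_real_ else r
}

#' Export a network and its centralities
#'
#' @param net a `threshold_network`.
#' @param profile optional `centrality_profile` for the per-node CSV.
#' @param graphml_path,edges_path,centrality_path output paths (each
#'   optional).
#' @return Invisibly, the list of paths written.
#' @export
write_network <- function(net, profile = NULL, graphml_path = NULL,
                          edges_path = NULL, centrality_path = NULL) {
  written <- list()
  ids <- igraph::V(net$graph)$name %||% as.character(seq_len(net$n_nodes))
  if (!is.null(graphml_path)) {
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
    written$graphml <- graphml_path
  }
  if (!is.null(edges_path)) {
    el <- igraph::as_edgelist(net$graph, names = TRUE)
    write.csv(data.frame(id_i = el[, 1], id_j = el[, 2]), edges_path,
              row.names = FALSE)
    written$edges <- edges_path
  }
  if (!is.null(centrality_path) && !is.null(profile)) {
    write.csv(data.frame(node_id = ids, degree = profile$degree,
                         betweenness = profile$betweenness,
                         eigenvector = profile$eigenvector),
              centrality_path, row.names = FALSE)
    written$centrality <- centrality_path
  }
  invisible(written)
}
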