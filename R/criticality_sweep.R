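# Threshold sweep against an ER ensemble and critical-point detection.
#
# For each cut-off t the CSN summaries (E, p, node-mean centralities,
# giant-component fraction, assortativity) are compared with a G(N, E(t))
# ensemble: same order, exactly the same number of edges, so mean-degree
# parity is exact and any excess structure (assortativity, communities) is
# attributable to the similarity geometry, not the edge budget.

sweep_metrics <- c("mean_degree", "mean_betweenness", "mean_eigenvector",
                   "giant_fraction", "assortativity")

network_summary <- function(net) {
  prof <- centrality_profile(net)
  c(E = net$E, p = net$p,
    mean_degree = prof$mean_degree,
    mean_betweenness = prof$mean_betweenness,
    mean_eigenvector = prof$mean_eigenvector,
    giant_fraction = giant_component_fraction(net),
    assortativity = assortativity_degree_safe(net))
}

#' Sweep the similarity threshold against an ER null ensemble
#'
#' For every threshold on the grid, builds the CSN, summarises it, samples
#' `n_er` uniform G(N, E(t)) replicates and summarises them as ensemble
#' mean and standard deviation. Each metric curve is additionally min-max
#' rescaled to `[0, 1]` across the grid (separately for CSN and ER) for
#' cross-metric comparison. Deterministic under `seed`: one sub-seed is
#' fanned out per (threshold, replicate).
#'
#' @param store a `similarity_store`.
#' @param grid ascending thresholds within `[floor, 1]`.
#' @param n_er ER replicates per threshold (default 20).
#' @param seed master seed.
#' @return A `sweep_result`: list with `thresholds`, `csn` (data frame,
#'   one row per threshold), `er_mean`, `er_sd`, `n_er`, and `scaled`
#'   (list of min-max rescaled curves `csn` and `er`).
#' @export
threshold_sweep <- function(store, grid = seq(0.30, 1.00, by = 0.01),
                            n_er = 20, seed = 1) {
  stopifnot(length(grid) >= 1, n_er >= 1)
  grid <- sort(grid)
  if (any(grid < store$floor) || any(grid > 1)) {
    stop("sweep grid must lie within [floor, 1]")
  }
  n <- store$n_molecules
  csn <- matrix(NA_real_, length(grid), 7,
                dimnames = list(NULL, c("E", "p", sweep_metrics)))
  er_mean <- csn; er_sd <- csn
  for (k in seq_along(grid)) {
    net <- build_network(store, grid[k])
    csn[k, ] <- network_summary(net)
    reps <- matrix(NA_real_, n_er, 7)
    for (r in seq_len(n_er)) {
      er <- sample_er(n, net$E, seed = derive_seed(seed, k, r))
      reps[r, ] <- network_summary(er)
    }
    er_mean[k, ] <- colMeans(reps, na.rm = TRUE)
    er_sd[k, ] <- apply(reps, 2, sd, na.rm = TRUE)
  }
  scaled <- list(
    csn = apply(csn[, sweep_metrics, drop = FALSE], 2, scale_unit),
    er = apply(er_mean[, sweep_metrics, drop = FALSE], 2, scale_unit)
  )
  structure(
    list(thresholds = grid,
         csn = as.data.frame(cbind(threshold = grid, csn)),
         er_mean = as.data.frame(cbind(threshold = grid, er_mean)),
         er_sd = as.data.frame(cbind(threshold = grid, er_sd)),
         n_er = n_er, seed = seed, n_nodes = n),
    class = "sweep_result"
  ) -> out
  out$scaled <- scaled
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", length(x$thresholds), " thresholds in [",
      min(x$thresholds), ", ", max(x$thresholds), "], N = ", x$n_nodes,
      ", ER ensemble of ", x$n_er, "\n", sep = "")
  invisible(x)
}

#' Locate the critical threshold of a sweep
#'
#' The phase transition is read off the sweep by one of three criteria:
#' `betweenness_peak` (argmax of the CSN mean betweenness — the primary
#' optimal-cut-off signal), `assortativity_peak` (argmax of CSN
#' assortativity), or `giant_onset` (the largest threshold at which the
#' giant-component fraction still exceeds `onset_fraction`, i.e. where the
#' giant component first appears coming from the sparse side). Ties break
#' toward the larger threshold (sparser network).
#'
#' @param sweep a `sweep_result` with at least 3 grid points.
#' @param criterion one of `"betweenness_peak"`, `"assortativity_peak"`,
#'   `"giant_onset"`.
#' @param onset_fraction giant-fraction onset level for `giant_onset`.
#' @return A `critical_point`: list `t_crit`, `p_crit`, `criterion`,
#'   `found`. An all-flat curve yields `found = FALSE` with `NA`
#'   coordinates (explicit no-transition result).
#' @export
detect_critical_point <- function(sweep,
                                  criterion = c("betweenness_peak",
                                                "assortativity_peak",
                                                "giant_onset"),
                                  onset_fraction = 0.05) {
  criterion <- match.arg(criterion)
  stopifnot(length(sweep$thresholds) >= 3)
  t <- sweep$thresholds
  curve <- switch(criterion,
    betweenness_peak = sweep$csn$mean_betweenness,
    assortativity_peak = sweep$csn$assortativity,
    giant_onset = sweep$csn$giant_fraction
  )
  no_transition <- function() {
    structure(list(t_crit = NA_real_, p_crit = NA_real_,
                   criterion = criterion, found = FALSE),
              class = "critical_point")
  }
  if (all(is.na(curve))) return(no_transition())
  if (criterion == "giant_onset") {
    ok <- which(!is.na(curve) & curve > onset_fraction)
    if (length(ok) == 0) return(no_transition())
    k <- max(ok)
  } else {
    if (diff(range(curve, na.rm = TRUE)) == 0) return(no_transition())
    mx <- max(curve, na.rm = TRUE)
    k <- max(which(curve == mx))  # ties toward larger threshold
  }
  structure(
    list(t_crit = t[k], p_crit = sweep$csn$p[k], criterion = criterion,
         found = TRUE),
    class = "critical_point"
  )
}

#' @export
print.critical_point <- function(x, ...) {
  if (x$found) {
    cat("<critical_point> t_crit = ", x$t_crit, ", p_crit = ",
        signif(x$p_crit, 4), " (", x$criterion, ")\n", sep = "")
  } else {
    cat("<critical_point> no transition detected (", x$criterion, ")\n",
        sep = "")
  }
  invisible(x)
}

#' ER percolation diagnostics over a connection-probability grid
#'
#' Pure-null companion of [threshold_sweep()]: for each connection
#' probability `p` it samples `n_rep` uniform G(N, E = round(p * E_max))
#' graphs and records the ensemble mean giant-component fraction and mean
#' betweenness. Used to verify that the giant-component onset and the
#' betweenness peak both sit at the ER critical probability of order
#' `1/N`.
#'
#' @param n number of nodes.
#' @param p_grid ascending connection probabilities.
#' @param n_rep replicates per grid point (default 20).
#' @param seed master seed.
#' @param onset_fraction giant-fraction level defining the onset.
#' @return A list with the diagnostics data frame `curve` (columns `p`,
#'   `giant_fraction`, `mean_betweenness`, ensemble sds), `p_onset`
#'   (smallest grid `p` whose mean giant fraction exceeds
#'   `onset_fraction`), and `p_betweenness_peak` (grid `p` maximising the
#'   mean betweenness).
#' @export
er_criticality <- function(n, p_grid, n_rep = 20, seed = 1,
                           onset_fraction = 0.05) {
  p_grid <- sort(p_grid)
  emax <- n * (n - 1) / 2
  gf <- numeric(length(p_grid)); gf_sd <- numeric(length(p_grid))
  bt <- numeric(length(p_grid)); bt_sd <- numeric(length(p_grid))
  for (k in seq_along(p_grid)) {
    e <- round(p_grid[k] * emax)
    reps_g <- numeric(n_rep); reps_b <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      net <- sample_er(n, e, seed = derive_seed(seed, k, r))
      reps_g[r] <- giant_component_fraction(net)
      reps_b[r] <- mean(igraph::betweenness(net$graph, directed = FALSE,
                                            normalized = FALSE))
    }
    gf[k] <- mean(reps_g); gf_sd[k] <- sd(reps_g)
    bt[k] <- mean(reps_b); bt_sd[k] <- sd(reps_b)
  }
  onset <- which(gf > onset_fraction)
  list(
    curve = data.frame(p = p_grid, giant_fraction = gf,
                       giant_fraction_sd = gf_sd, mean_betweenness = bt,
                       mean_betweenness_sd = bt_sd),
    p_onset = if (length(onset)) p_grid[min(onset)] else NA_real_,
    p_betweenness_peak = p_grid[which.max(bt)]
  )
}

#' Write a sweep as tidy CSV and a critical point as JSON
#'
#' The CSV is long-format with columns
#' `threshold,p,model,metric,value,sd` (`model` is `csn` or `er`; `sd` is
#' `NA` for the single observed CSN).
#'
#' @param sweep a `sweep_result`.
#' @param csv_path tidy CSV output path.
#' @param critical optional `critical_point`.
#' @param critical_path optional JSON path for the critical point.
#' @return `csv_path`, invisibly.
#' @export
write_sweep <- function(sweep, csv_path, critical = NULL,
                        critical_path = NULL) {
  long <- function(df, model, sd_df = NULL) {
    do.call(rbind, lapply(c("E", sweep_metrics), function(m) {
      data.frame(threshold = df$threshold, p = df$p, model = model,
                 metric = m, value = df[[m]],
                 sd = if (is.null(sd_df)) NA_real_ else sd_df[[m]])
    }))
  }
  tidy <- rbind(long(sweep$csn, "csn"),
                long(sweep$er_mean, "er", sweep$er_sd))
  write.csv(tidy, csv_path, row.names = FALSE)
  if (!is.null(critical) && !is.null(critical_path)) {
    jsonlite::write_json(
      list(t_crit = critical$t_crit, p_crit = critical$p_crit,
           criterion = critical$criterion, found = critical$found),
      critical_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(csv_path)
}
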