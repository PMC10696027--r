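# End-to-end orchestration: curate -> similarities -> sweep -> critical
# point -> communities -> descriptor screen -> classification, with a
# checksummed manifest so a rerun with the same config reproduces
# identical artifacts.

#' Compute a small set of 2D molecular descriptors
#'
#' Physicochemical descriptors from OpenBabel (molecular weight, logP,
#' topological polar surface area, molar refractivity, H-bond
#' acceptors/donors, rotatable bonds) plus graph-topological counts
#' derived from the hydrogen-suppressed molecular graph (heavy atoms,
#' bonds, rings by cyclomatic number, aromatic-atom fraction, heteroatom
#' fraction, halogen count). Intended for the community descriptor
#' screen; any externally computed numeric descriptor table can be used
#' instead.
#'
#' @param smiles character vector of (canonical) SMILES.
#' @return Data frame of numeric descriptors, one row per molecule.
#' @export
compute_descriptors <- function(smiles) {
  n <- length(smiles)
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles, paste0("row", seq_len(n))), infile)
  fields <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBD", "rotors")
  out <- system2(obabel_path(),
                 c(infile, "-otxt", "-e",
                   "--append", shQuote(paste(fields, collapse = " "))),
                 stdout = TRUE, stderr = FALSE)
  ob <- matrix(NA_real_, n, length(fields),
               dimnames = list(NULL, c("mol_weight", "logp", "tpsa",
                                       "molar_refractivity", "hba", "hbd",
                                       "rotatable_bonds")))
  for (line in out) {
    f <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(f) == length(fields) + 1 && grepl("^row[0-9]+$", f[1])) {
      ob[as.integer(sub("^row", "", f[1])), ] <-
        suppressWarnings(as.numeric(f[-1]))
    }
  }
  graphs <- smiles_to_graph(smiles)
  if (n == 1) graphs <- list(graphs)
  topo <- t(vapply(graphs, function(g) {
    if (is.null(g)) return(rep(NA_real_, 6))
    nb <- nrow(g$bonds)
    comp_n <- 1  # canonical input is single-fragment
    c(n_atoms = g$size, n_bonds = nb,
      n_rings = nb - g$size + comp_n,
      aromatic_fraction = if (g$size) mean(g$aromatic) else 0,
      heteroatom_fraction = if (g$size) mean(!g$elements %in% "C") else 0,
      n_halogens = sum(g$elements %in% c("F", "Cl", "Br", "I")))
  }, numeric(6)))
  cbind(as.data.frame(ob), as.data.frame(topo))
}

#' Assemble a pipeline run configuration
#'
#' Defaults: similarity floor 0.3, threshold
#' grid 0.30..1.00 in steps of 0.01, 20 ER replicates, 80% stratified
#' hold-out iterated 100 times, screen at alpha 0.01 over the top 3
#' communities.
#'
#' @param input a `molecule_set`, or a path to a labelled SMILES table
#'   readable by [read_smiles_table()].
#' @param out_dir output directory for stage artifacts.
#' @param floor similarity floor.
#' @param grid threshold grid.
#' @param er_replicates ER replicates per threshold.
#' @param holdout training fraction.
#' @param cv_iterations hold-out iterations.
#' @param alpha screen significance level.
#' @param top_k communities screened.
#' @param seed master seed.
#' @param mcs_max_expansions per-pair cap for the exact MCS search.
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir,
                       floor = 0.3,
                       grid = seq(0.30, 1.00, by = 0.01),
                       er_replicates = 20,
                       holdout = 0.8,
                       cv_iterations = 100,
                       alpha = 0.01,
                       top_k = 3,
                       seed = 42,
                       mcs_max_expansions = 2e6) {
  if (any(grid < floor)) stop("threshold grid extends below the floor")
  structure(
    list(input = input, out_dir = out_dir, floor = floor, grid = grid,
         er_replicates = er_replicates, holdout = holdout,
         cv_iterations = cv_iterations, alpha = alpha, top_k = top_k,
         seed = seed, mcs_max_expansions = mcs_max_expansions),
    class = "run_config"
  )
}

#' Run the full CSN analysis pipeline
#'
#' Executes curate, similarity, sweep, critical point, communities,
#' descriptor screen and classification in order, writing each stage's
#' artifact under `config$out_dir` and returning a manifest with
#' parameter values, seeds and per-file MD5 checksums. A rerun with an
#' identical config reproduces identical checksums. The screen and
#' classification stages degrade gracefully (recorded as skipped in the
#' manifest) when their preconditions fail — e.g. fewer than `top_k`
#' communities, or a single-class label set.
#'
#' @param config a [run_config()].
#' @return The manifest (list), invisibly written to
#'   `manifest.json` as well.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  manifest <- list(parameters = config[setdiff(names(config), "input")],
                   stages = list())

  # curate
  mols <- if (inherits(config$input, "molecule_set")) config$input
          else read_smiles_table(config$input)
  merged <- merge_and_deduplicate(list(mols))
  mols <- merged$molecules
  write_molecule_set(mols, path("curated.csv"), merged$conflicts,
                     path("conflicts.json"))
  manifest$stages$curate <- list(
    file = "curated.csv", n_molecules = nrow(mols),
    n_conflicts = merged$conflicts$n_discarded
  )

  # similarity
  store <- pairwise_similarity(mols, floor = config$floor,
                               max_expansions = config$mcs_max_expansions)
  write_similarity_store(store, path("edges.csv"), path("edges_meta.json"))
  manifest$stages$similarity <- list(
    file = "edges.csv", n_pairs = nrow(store$pairs),
    n_timeouts = nrow(store$timeouts)
  )

  # sweep + critical point
  sweep <- threshold_sweep(store, grid = config$grid,
                           n_er = config$er_replicates,
                           seed = derive_seed(config$seed, 1))
  crit <- detect_critical_point(sweep, "betweenness_peak")
  write_sweep(sweep, path("sweep.csv"), crit, path("critical_point.json"))
  manifest$stages$sweep <- list(
    file = "sweep.csv", t_crit = crit$t_crit, p_crit = crit$p_crit,
    found = crit$found
  )
  t_star <- if (crit$found) crit$t_crit else config$floor

  # communities at criticality
  net <- build_network(store, t_star)
  part <- louvain_partition(net, seed = derive_seed(config$seed, 2))
  write_partition(part, mols$id, path("communities.csv"),
                  path("communities.json"))
  manifest$stages$communities <- list(
    file = "communities.csv", modularity = part$modularity,
    top_sizes = utils::head(part$sizes, config$top_k),
    fraction_connected = part$fraction_connected
  )

  # descriptor screen
  screen_ok <- part$n_communities >= config$top_k &&
    all(utils::head(part$sizes, config$top_k) >= 5)
  if (screen_ok) {
    desc <- compute_descriptors(mols$smiles_canonical)
    desc <- descriptor_filter(desc, 0.10)
    screen <- tryCatch(
      community_descriptor_screen(desc, part, top_k = config$top_k,
                                  alpha = config$alpha),
      error = function(e) NULL
    )
    if (!is.null(screen)) {
      write.csv(as.data.frame(screen), path("screen.csv"),
                row.names = FALSE)
      manifest$stages$screen <- list(
        file = "screen.csv", n_descriptors = nrow(screen),
        n_significant = sum(screen$significant)
      )
    } else screen_ok <- FALSE
  }
  if (!screen_ok) manifest$stages$screen <- list(skipped = TRUE)

  # classification
  has_both <- all(c("toxic", "nontoxic") %in% mols$label)
  if (has_both) {
    cv <- holdout_cv(store, t = t_star, holdout = config$holdout,
                     iters = config$cv_iterations,
                     seed = derive_seed(config$seed, 3))
    write.csv(
      data.frame(threshold = t_star, metric = names(cv$mean),
                 mean = as.numeric(cv$mean), sd = as.numeric(cv$sd)),
      path("classification.csv"), row.names = FALSE
    )
    manifest$stages$classification <- c(
      list(file = "classification.csv"), as.list(cv$mean)
    )
  } else {
    manifest$stages$classification <- list(skipped = TRUE)
  }

  files <- vapply(manifest$stages,
                  function(s) s$file %||% NA_character_, "")
  files <- files[!is.na(files)]
  manifest$checksums <- as.list(tools::md5sum(file.path(config$out_dir,
                                                        files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
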