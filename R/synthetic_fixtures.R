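# Synthetic inputs with planted family structure.
#
# Two generators: a chemical one (scaffold families with random
# decorations, so within-family MCS-Tanimoto is high and cross-family
# low) and an abstract one (a similarity store with block structure and
# no chemistry at all), so the network/statistics layers can be tested
# without ever touching the MCS engine.

#' Specify a scaffold family
#'
#' A family is a scaffold SMILES template containing `{k}` substitution
#' slots, a set of substituent fragments, and a label. Members are built
#' by filling a random subset of slots with random fragments, so all
#' members share the scaffold core (guaranteeing high within-family
#' MCS-Tanimoto) and differ in their decorations.
#'
#' @param scaffold SMILES template with slots written `{1}`, `{2}`, ...;
#'   a slot filled with fragment `X` becomes the branch `(X)`, an unused
#'   slot disappears.
#' @param n_members number of distinct molecules to generate.
#' @param decorations character vector of substituent fragments (plain
#'   single-attachment SMILES like `"C"`, `"CC"`, `"O"`, `"Cl"`).
#' @param decoration_range integer range (min, max) of slots decorated per
#'   molecule.
#' @param label `"toxic"` or `"nontoxic"`.
#' @param label_noise probability in `[0, 0.5)` that a member's label is
#'   flipped.
#' @param name family name.
#' @return A `family_spec` list.
#' @export
family_spec <- function(scaffold, n_members,
                        decorations = c("C", "CC", "O", "N", "Cl"),
                        decoration_range = c(1, 2),
                        label = "toxic", label_noise = 0,
                        name = "family") {
  stopifnot(n_members >= 1, label %in% c("toxic", "nontoxic"),
            label_noise >= 0, label_noise < 0.5)
  n_slots <- length(gregexpr("\\{[0-9]+\\}", scaffold)[[1]])
  stopifnot(grepl("\\{1\\}", scaffold))
  structure(
    list(scaffold = scaffold, n_members = n_members,
         decorations = decorations,
         decoration_range = pmin(decoration_range, n_slots),
         label = label, label_noise = label_noise, name = name,
         n_slots = n_slots),
    class = "family_spec"
  )
}

fill_scaffold <- function(spec) {
  n_dec <- sample(seq(spec$decoration_range[1], spec$decoration_range[2]), 1)
  slots <- sample(spec$n_slots, min(n_dec, spec$n_slots))
  smi <- spec$scaffold
  for (k in seq_len(spec$n_slots)) {
    frag <- if (k %in% slots) {
      paste0("(", sample(spec$decorations, 1), ")")
    } else ""
    smi <- sub(paste0("\\{", k, "\\}"), frag, smi, fixed = FALSE)
  }
  smi
}

#' Generate labelled molecules from scaffold families
#'
#' Emits `n_members` distinct molecules per family by attaching random
#' decorations to the family scaffold; records carry the family name as
#' `source` and a label flipped with probability `label_noise`.
#' Reproducible under `seed`. Decoration draws that fail to parse or
#' collide with an existing member are retried; after `max_tries`
#' attempts the family is emitted smaller with a message.
#'
#' @param specs list of [family_spec()] objects (scaffolds should be
#'   structurally dissimilar).
#' @param seed integer seed.
#' @param max_tries random decoration draws per family before giving up
#'   (drawn in batches; duplicates after canonicalisation do not count).
#' @return A `molecule_set` with one record per generated molecule;
#'   `source` holds the family name, so planted membership is
#'   recoverable.
#' @export
generate_scaffold_families <- function(specs, seed = 1, max_tries = 2000) {
  if (inherits(specs, "family_spec")) specs <- list(specs)
  set.seed(seed)
  smiles <- character(0); label <- character(0); fam <- character(0)
  for (spec in specs) {
    got <- character(0)        # kept raw SMILES
    seen_canon <- character(0) # their canonical forms
    seen_raw <- character(0)   # every raw string tried
    tries <- 0
    while (length(got) < spec$n_members && tries < max_tries) {
      batch <- unique(replicate(50, fill_scaffold(spec)))
      tries <- tries + 50
      batch <- setdiff(batch, seen_raw)
      seen_raw <- c(seen_raw, batch)
      if (length(batch) == 0) next
      canon <- canonicalize_smiles(batch)
      ok <- which(!is.na(canon) & !duplicated(canon) &
                    !canon %in% seen_canon)
      ok <- ok[seq_len(min(length(ok), spec$n_members - length(got)))]
      got <- c(got, batch[ok])
      seen_canon <- c(seen_canon, canon[ok])
    }
    if (length(got) < spec$n_members) {
      message("family '", spec$name, "': generated ", length(got), " of ",
              spec$n_members, " requested members")
    }
    labs <- rep(spec$label, length(got))
    flip <- stats::runif(length(got)) < spec$label_noise
    labs[flip] <- ifelse(labs[flip] == "toxic", "nontoxic", "toxic")
    smiles <- c(smiles, got)
    label <- c(label, labs)
    fam <- c(fam, rep(spec$name, length(got)))
  }
  molecule_set(smiles, label = label, source = fam)
}

#' The three-archetypes synthetic preset
#'
#' Echoes, at toy scale, the archetype structure seen in developmental-
#' toxicity chemical space networks: an aromatic (aryl) family, a fused
#' bicyclic (steroid-like) family — both labelled toxic — and a small
#' ether/VOC-like family labelled nontoxic. The scaffolds use mutually
#' incompatible bond chemistry (aromatic ring vs saturated fused rings vs
#' short ether chain) so cross-family MCS-Tanimoto stays below the 0.3
#' similarity floor while within-family similarity is high. No
#' toxicological meaning is claimed for the toy structures.
#'
#' @param n_members family sizes (aryl, fused-bicyclic, ether).
#' @param label_noise label flip probability (default 0.02, a small
#'   experimental-label error rate).
#' @param seed integer seed.
#' @return A `molecule_set`.
#' @export
three_archetypes <- function(n_members = c(25, 20, 15), label_noise = 0.02,
                             seed = 1) {
  specs <- list(
    family_spec("c1c{1}c{2}cc{3}c1", n_members[1],
                decorations = c("C", "CC", "O", "N", "Cl", "F", "CO"),
                decoration_range = c(1, 3), label = "toxic",
                label_noise = label_noise, name = "aryl"),
    family_spec("C1CC{1}C2CC{3}C{2}CC2C1", n_members[2],
                decorations = c("C", "O", "CC", "N", "F"),
                decoration_range = c(1, 2), label = "toxic",
                label_noise = label_noise, name = "fused_bicyclic"),
    family_spec("C{1}C{2}OCC{3}", n_members[3],
                decorations = c("C", "O", "Cl", "N", "F"),
                decoration_range = c(1, 2), label = "nontoxic",
                label_noise = label_noise, name = "ether")
  )
  generate_scaffold_families(specs, seed = seed)
}

#' Generate an abstract planted-block similarity store
#'
#' Builds a similarity store with no molecules behind it: within-family
#' pair similarities are uniform in `within_range`, cross-family pairs
#' uniform in `between_range` (strictly below the within range), and
#' values at or below `floor` are dropped per the store convention. Any
#' threshold inside the gap separates the families into disjoint dense
#' blocks.
#'
#' @param n_families number of families.
#' @param family_size members per family (scalar or vector).
#' @param within_range similarity range `(lo, hi)` for within-family
#'   pairs.
#' @param between_range similarity range for cross-family pairs; must lie
#'   strictly below `within_range`.
#' @param floor store floor (default 0.3).
#' @param labels optional per-family labels (recycled).
#' @param seed integer seed.
#' @return A `similarity_store` whose `labels` carry the family labels
#'   and with attribute `family` (planted membership).
#' @export
generate_planted_store <- function(n_families = 3, family_size = 20,
                                   within_range = c(0.75, 0.95),
                                   between_range = c(0.30, 0.45),
                                   floor = 0.3, labels = "toxic",
                                   seed = 1) {
  stopifnot(within_range[1] < within_range[2],
            between_range[1] < between_range[2])
  if (between_range[2] >= within_range[1]) {
    stop("between_range must lie strictly below within_range")
  }
  family_size <- rep_len(family_size, n_families)
  labels <- rep_len(labels, n_families)
  n <- sum(family_size)
  fam <- rep(seq_len(n_families), family_size)
  set.seed(seed)
  ii <- integer(0); jj <- integer(0); ss <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      rng <- if (fam[i] == fam[j]) within_range else between_range
      s <- stats::runif(1, rng[1], rng[2])
      if (s > floor) {
        ii <- c(ii, i); jj <- c(jj, j); ss <- c(ss, s)
      }
    }
  }
  store <- similarity_store(
    n_molecules = n, ids = paste0("m", seq_len(n)),
    labels = labels[fam], floor = floor,
    pairs = data.frame(i = ii, j = jj, similarity = ss)
  )
  attr(store, "family") <- fam
  store
}
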