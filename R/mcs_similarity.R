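# SMSD-style maximum common subgraph (MCS) Tanimoto similarity.
#
# Molecules are hydrogen-suppressed molecular graphs: heavy atoms carry an
# element symbol and an aromatic flag, bonds carry an order in
# {single, double, triple, aromatic}. Aromaticity is perceived by OpenBabel
# (mol2 export), so matching is Kekule-insensitive: aromatic is its own
# bond order.

BOND_ORDER_CODES <- c("1" = 1L, "2" = 2L, "3" = 3L, "am" = 1L, "ar" = 4L,
                      "du" = 1L, "un" = 1L)

#' Convert SMILES to hydrogen-suppressed molecular graphs
#'
#' Parses each SMILES with OpenBabel and extracts the heavy-atom graph with
#' perceived aromaticity: atoms are (element, aromatic flag), bonds carry
#' order single/double/triple/aromatic. Hydrogens are implicit.
#'
#' @param smiles character vector of SMILES.
#' @return A list of `molecular_graph` objects (fields `elements`,
#'   `aromatic`, `bonds` — integer matrix `i,j,order` with order 4 =
#'   aromatic — and `size`, the heavy-atom count), `NULL` for unparseable
#'   inputs. For a single SMILES the graph itself is returned.
#' @examples
#' \dontrun{
#' g <- smiles_to_graph("c1ccccc1")
#' g$size            # 6
#' }
#' @export
smiles_to_graph <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0) return(list())
  lines <- obabel_convert(smiles, "mol2")
  out <- vector("list", n)
  if (length(lines)) {
    starts <- grep("^@<TRIPOS>MOLECULE", lines)
    ends <- c(starts[-1] - 1L, length(lines))
    for (k in seq_along(starts)) {
      block <- lines[starts[k]:ends[k]]
      name <- trimws(block[2])
      if (!grepl("^row[0-9]+$", name)) next
      idx <- as.integer(sub("^row", "", name))
      out[[idx]] <- parse_mol2_block(block)
    }
  }
  if (n == 1) out[[1]] else out
}

parse_mol2_block <- function(block) {
  counts <- as.integer(strsplit(trimws(block[3]), "[ \t]+")[[1]])
  natoms <- counts[1]; nbonds <- counts[2]
  a0 <- grep("^@<TRIPOS>ATOM", block)[1]
  elements <- character(natoms); aromatic <- logical(natoms)
  if (natoms > 0) {
    for (i in seq_len(natoms)) {
      f <- strsplit(trimws(block[a0 + i]), "[ \t]+")[[1]]
      type <- f[6]
      elements[i] <- sub("\\..*$", "", type)
      aromatic[i] <- grepl("\\.ar$", type)
    }
  }
  bonds <- matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("i", "j", "order")))
  b0 <- grep("^@<TRIPOS>BOND", block)
  if (length(b0) && nbonds > 0) {
    bonds <- matrix(0L, nrow = nbonds, ncol = 3,
                    dimnames = list(NULL, c("i", "j", "order")))
    for (r in seq_len(nbonds)) {
      f <- strsplit(trimws(block[b0[1] + r]), "[ \t]+")[[1]]
      ord <- BOND_ORDER_CODES[f[4]]
      if (is.na(ord)) ord <- 1L
      bonds[r, ] <- c(as.integer(f[2]), as.integer(f[3]), ord)
    }
  }
  structure(
    list(elements = elements, aromatic = aromatic, bonds = bonds,
         size = natoms),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$size, " heavy atoms, ", nrow(x$bonds),
      " bonds (", sum(x$bonds[, "order"] == 4L), " aromatic)\n", sep = "")
  invisible(x)
}

as_molecular_graph <- function(x) {
  if (inherits(x, "molecular_graph")) return(x)
  if (is.character(x) && length(x) == 1) {
    g <- smiles_to_graph(x)
    if (is.null(g)) stop("unparseable SMILES: '", x, "'")
    return(g)
  }
  stop("expected a molecular_graph or a single SMILES string")
}

# encode element symbols of two graphs on a shared integer alphabet
encode_elements <- function(a, b) {
  alphabet <- union(a$elements, b$elements)
  list(a = match(a$elements, alphabet), b = match(b$elements, alphabet))
}

#' Maximum common connected subgraph size
#'
#' Exact size (in heavy atoms) of a largest connected common induced
#' subgraph of two molecular graphs under element-exact atom matching and
#' order-exact bond matching (aromatic is its own order; absence of a
#' bond must also agree, so similarity 1 occurs iff the heavy-atom graphs
#' are isomorphic). The search is a
#' branch-and-bound over connected mapping extensions; a per-pair
#' node-expansion cap guards against pathological pairs and raises an
#' explicit error when exceeded — never a silent approximation.
#'
#' @param a,b `molecular_graph` objects (or single SMILES strings).
#' @param max_expansions node-expansion cap for the exact search.
#' @return Non-negative integer MCS size.
#' @examples
#' \dontrun{
#' mcs_size("CC", "CCC")             # 2
#' mcs_size("c1ccccc1", "Cc1ccccc1") # 6
#' }
#' @export
mcs_size <- function(a, b, max_expansions = 2e6) {
  a <- as_molecular_graph(a); b <- as_molecular_graph(b)
  if (a$size == 0 || b$size == 0) return(0L)
  enc <- encode_elements(a, b)
  res <- mcs_size_cpp(enc$a, a$bonds, enc$b, b$bonds, max_expansions)
  if (res$capped) {
    stop("MCS search exceeded the node-expansion cap (",
         format(max_expansions, scientific = FALSE), ") for this pair")
  }
  as.integer(res$size)
}

#' MCS-based Tanimoto similarity between two molecules
#'
#' `m / (|A| + |B| - m)` where `m` is the maximum common connected subgraph
#' size in heavy atoms: the share of the union of the two molecular graphs
#' covered by their common core. Symmetric; 1 iff the graphs are
#' isomorphic (in the heavy-atom, bond-order sense).
#'
#' @inheritParams mcs_size
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto_smsd <- function(a, b, max_expansions = 2e6) {
  a <- as_molecular_graph(a); b <- as_molecular_graph(b)
  stopifnot(a$size > 0, b$size > 0)
  m <- mcs_size(a, b, max_expansions)
  m / (a$size + b$size - m)
}

#' Floored sparse pairwise MCS-Tanimoto matrix
#'
#' Evaluates all `N(N-1)/2` pairwise similarities of a molecule set and
#' stores only values strictly greater than `floor` (the default
#' floor of 0.3 treats lower similarities as uninformative, which
#' also bounds the quadratic cost of everything downstream). Pairs whose
#' exact MCS search exceeds the node-expansion cap are recorded as missing
#' with a reason, never silently set to zero. A cheap upper bound
#' `min(|A|,|B|) / max(|A|,|B|)` skips pairs that cannot clear the floor.
#'
#' @param mols a `molecule_set` (or character vector of SMILES).
#' @param floor similarity floor in `[0, 1)`; only values `> floor` are
#'   stored.
#' @param max_expansions per-pair cap for the exact MCS search.
#' @param progress print a progress message every `progress` pairs (0 =
#'   silent).
#' @return A `similarity_store`: list with `n_molecules`, `ids`, `labels`,
#'   `floor`, `pairs` (data frame `i`, `j`, `similarity` with `i < j`) and
#'   `timeouts` (data frame of skipped pairs).
#' @export
pairwise_similarity <- function(mols, floor = 0.3, max_expansions = 2e6,
                                progress = 0) {
  if (is.character(mols)) mols <- molecule_set(mols)
  stopifnot(inherits(mols, "molecule_set"), nrow(mols) >= 2,
            floor >= 0, floor < 1)
  graphs <- smiles_to_graph(mols$smiles_canonical)
  if (nrow(mols) == 1) graphs <- list(graphs)
  sizes <- vapply(graphs, function(g) if (is.null(g)) 0L else g$size, 0L)
  n <- nrow(mols)
  ii <- integer(0); jj <- integer(0); ss <- numeric(0)
  ti <- integer(0); tj <- integer(0)
  done <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      done <- done + 1L
      if (progress > 0 && done %% progress == 0) {
        message("pairwise_similarity: ", done, "/", n * (n - 1) / 2, " pairs")
      }
      if (sizes[i] == 0 || sizes[j] == 0) next
      bound <- min(sizes[i], sizes[j]) / max(sizes[i], sizes[j])
      if (bound <= floor) next
      s <- tryCatch(
        tanimoto_smsd(graphs[[i]], graphs[[j]], max_expansions),
        error = function(e) NA_real_
      )
      if (is.na(s)) {
        ti <- c(ti, i); tj <- c(tj, j)
      } else if (s > floor) {
        ii <- c(ii, i); jj <- c(jj, j); ss <- c(ss, s)
      }
    }
  }
  similarity_store(
    n_molecules = n, ids = mols$id, labels = mols$label, floor = floor,
    pairs = data.frame(i = ii, j = jj, similarity = ss),
    timeouts = data.frame(i = ti, j = tj)
  )
}

#' Construct a similarity store
#'
#' Container for the sparse floored pairwise similarity matrix: entries are
#' unordered molecule pairs (`i < j`) with similarity strictly above the
#' floor. Symmetry is by construction (only `i < j` is stored).
#'
#' @param n_molecules number of molecules.
#' @param ids molecule ids (length `n_molecules`).
#' @param labels optional molecule labels.
#' @param floor the similarity floor.
#' @param pairs data frame `i`, `j`, `similarity`.
#' @param timeouts data frame of pairs whose MCS search was capped.
#' @return A `similarity_store`.
#' @export
similarity_store <- function(n_molecules, ids = NULL, labels = NULL,
                             floor = 0.3, pairs, timeouts = NULL) {
  stopifnot(all(pairs$i < pairs$j), all(pairs$j <= n_molecules),
            all(pairs$similarity > floor), all(pairs$similarity <= 1))
  structure(
    list(
      n_molecules = as.integer(n_molecules),
      ids = ids %||% paste0("mol", seq_len(n_molecules)),
      labels = labels,
      floor = floor,
      pairs = pairs,
      timeouts = timeouts %||% data.frame(i = integer(0), j = integer(0))
    ),
    class = "similarity_store"
  )
}

#' @export
print.similarity_store <- function(x, ...) {
  cat("<similarity_store> ", x$n_molecules, " molecules, ",
      nrow(x$pairs), " pairs > floor ", x$floor,
      " (", nrow(x$timeouts), " timeouts)\n", sep = "")
  invisible(x)
}

#' Write / read a similarity store as edge CSV plus JSON metadata
#'
#' @param store a `similarity_store`.
#' @param csv_path edge file (`id_i,id_j,similarity`).
#' @param meta_path optional JSON metadata path.
#' @return `csv_path`, invisibly.
#' @export
write_similarity_store <- function(store, csv_path, meta_path = NULL) {
  edges <- data.frame(
    id_i = store$ids[store$pairs$i],
    id_j = store$ids[store$pairs$j],
    similarity = store$pairs$similarity
  )
  write.csv(edges, csv_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    jsonlite::write_json(
      list(n_molecules = store$n_molecules, floor = store$floor,
           n_pairs_stored = nrow(store$pairs),
           n_timeouts = nrow(store$timeouts),
           ids = store$ids, labels = store$labels),
      meta_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(csv_path)
}

#' @rdname write_similarity_store
#' @param meta_path JSON metadata written by [write_similarity_store()]
#'   (required for reading: it carries the node universe and floor).
#' @export
read_similarity_store <- function(csv_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  edges <- read.csv(csv_path, stringsAsFactors = FALSE)
  ids <- meta$ids
  similarity_store(
    n_molecules = meta$n_molecules, ids = ids, labels = meta$labels,
    floor = meta$floor,
    pairs = data.frame(
      i = match(edges$id_i, ids), j = match(edges$id_j, ids),
      similarity = edges$similarity
    )
  )
}
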