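# Shared fixtures and small utilities for the suite.

# the same molecular graph written with different atom orders / notations
smiles_rewrite_pairs <- list(
  c("OCC", "C(C)O"),
  c("CCO", "OCC"),
  c("CC(N)O", "C(O)(N)C"),
  c("C[C@H](N)O", "CC(N)O"),
  c("C(F)(F)F", "FC(F)F"),
  c("c1ccccc1", "c1ccccc1"),
  c("Cc1ccccc1", "c1ccc(C)cc1"),
  c("c1ccncc1", "n1ccccc1"),
  c("CC(=O)O", "OC(C)=O"),
  c("C/C=C/C", "CC=CC"),
  c("N#CC", "CC#N"),
  c("OCCN", "NCCO"),
  c("ClC(Cl)Cl", "C(Cl)(Cl)Cl"),
  c("CC(C)C", "C(C)(C)C"),
  c("C1CCCCC1", "C1CCCCC1"),
  c("C1CCOC1", "O1CCCC1"),
  c("CCOC", "COCC"),
  c("CCNC", "CNCC"),
  c("CC(C)=O", "O=C(C)C"),
  c("c1ccc2ccccc2c1", "c1ccc2c(c1)cccc2"),
  c("OC(=O)c1ccccc1", "c1ccccc1C(O)=O")
)

# a tiny abstract store: 3 nodes, pairs AB:0.9 AC:0.5 BC:0.31
tiny_store <- function() {
  similarity_store(
    n_molecules = 3, ids = c("A", "B", "C"), floor = 0.3,
    pairs = data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                       similarity = c(0.9, 0.5, 0.31))
  )
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

# deterministic cached copy of the three-archetypes preset + its store,
# generated once per test run (the MCS stage is the expensive part)
archetype_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mols <- three_archetypes(seed = 1)
      store <- pairwise_similarity(mols, floor = 0.3)
      cache <<- list(mols = mols, store = store)
    }
    cache
  }
})
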