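# Independent brute-force oracle for the maximum common connected induced
# subgraph, used to validate the branch-and-bound engine on small
# molecules. Deliberately a different algorithm family: top-down
# enumeration of k-subsets and element-compatible bijections with an
# explicit connectivity check, no shared code with the search under test.

order_matrix <- function(g) {
  n <- g$size
  m <- matrix(0L, n, n)
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds[r, "i"]; j <- g$bonds[r, "j"]; o <- g$bonds[r, "order"]
      m[i, j] <- o; m[j, i] <- o
    }
  }
  m
}

subset_connected <- function(om, idx) {
  k <- length(idx)
  if (k == 1) return(TRUE)
  sub <- om[idx, idx, drop = FALSE] > 0
  seen <- logical(k); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(sub[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# TRUE if some element-preserving bijection sa -> sb matches bond orders
# exactly (induced equality)
any_bijection <- function(ea, eb, Oa, Ob, sa, sb) {
  k <- length(sa)
  rec <- function(pos, used, map) {
    if (pos > k) return(TRUE)
    for (cand in seq_len(k)) {
      if (used[cand]) next
      if (ea[sa[pos]] != eb[sb[cand]]) next
      ok <- TRUE
      if (pos > 1) {
        for (q in seq_len(pos - 1)) {
          if (Oa[sa[pos], sa[q]] != Ob[sb[cand], sb[map[q]]]) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      used[cand] <- TRUE; map[pos] <- cand
      if (rec(pos + 1, used, map)) return(TRUE)
      used[cand] <- FALSE
    }
    FALSE
  }
  rec(1L, logical(k), integer(k))
}

oracle_mcs_size <- function(ga, gb) {
  Oa <- order_matrix(ga); Ob <- order_matrix(gb)
  na <- ga$size; nb <- gb$size
  for (k in seq(min(na, nb), 1)) {
    subsA <- utils::combn(na, k, simplify = FALSE)
    subsA <- Filter(function(s) subset_connected(Oa, s), subsA)
    if (length(subsA) == 0) next
    subsB <- utils::combn(nb, k, simplify = FALSE)
    subsB <- Filter(function(s) subset_connected(Ob, s), subsB)
    for (sa in subsA) {
      ea_sorted <- sort(ga$elements[sa])
      for (sb in subsB) {
        if (!identical(ea_sorted, sort(gb$elements[sb]))) next
        if (any_bijection(ga$elements, gb$elements, Oa, Ob, sa, sb)) {
          return(k)
        }
      }
    }
  }
  0L
}

# small molecules (<= 8 heavy atoms) for oracle comparisons
oracle_fixture_smiles <- c(
  "CCO", "CCN", "CCC", "CC(C)O", "c1ccccc1", "c1ccncc1", "C1CCCCC1",
  "CC(=O)O", "C=CC=C", "CC#N", "OCCO", "ClCC(C)O", "C1CCOC1", "CC(C)C"
)
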