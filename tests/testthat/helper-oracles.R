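# Independent oracles and small constructors shared across test files.

# Position-by-position Hamming count, independent of p_distance().
brute_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

# Union of the edges of every minimum spanning tree of the complete
# graph with distance matrix d, by exhaustive enumeration of spanning
# trees (feasible for n <= 6 nodes).
enumerate_msn_edges <- function(d) {
  n <- nrow(d)
  if (n == 1) return(matrix(integer(), ncol = 2))
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  subsets <- utils::combn(m, n - 1)
  is_spanning <- function(edge_idx) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (k in edge_idx) {
      ri <- find(pairs[k, 1])
      rj <- find(pairs[k, 2])
      if (ri == rj) return(FALSE)
      parent[ri] <- rj
    }
    TRUE
  }
  best <- Inf
  best_trees <- list()
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    if (!is_spanning(idx)) next
    w <- sum(d[pairs[idx, , drop = FALSE]])
    if (w < best - 1e-9) {
      best <- w
      best_trees <- list(idx)
    } else if (abs(w - best) <= 1e-9) {
      best_trees[[length(best_trees) + 1]] <- idx
    }
  }
  edges <- unique(do.call(rbind, lapply(best_trees, function(idx) {
    pairs[idx, , drop = FALSE]
  })))
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# A one-individual tissue genotype tibble.
make_genotype <- function(id = "X1", locus = "EF1a",
                          tissue = "hemolymph", alleles, freqs,
                          seqs = NULL) {
  if (is.null(seqs)) {
    bases <- rep(c("A", "C", "G", "T"), length.out = length(alleles))
    seqs <- vapply(seq_along(alleles), function(i) {
      strrep(bases[i], 30)
    }, character(1))
  }
  tibble::tibble(
    individual_id = id, locus = locus, tissue = tissue,
    allele = alleles, sequence = unname(seqs), frequency = freqs,
    origin = "host"
  )
}
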