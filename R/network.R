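# Minimum spanning haplotype network: the union of all minimum spanning
# trees over Hamming distances (so alternative equally parsimonious
# connections are retained), with multi-step edges expanded through
# inferred median (hypothetical) haplotypes. An optional maximum
# connection limit approximates the statistical-parsimony cutoff of
# TCS-style networks.

# Union of all MSTs of the complete graph on `n` nodes with distance
# matrix `d`: an edge (i, j) belongs to some MST iff i and j lie in
# different components of the graph restricted to edges strictly shorter
# than d[i, j]. Processed per distinct weight with union-find.
msn_edges <- function(d, max_steps = Inf) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w)
  pairs <- pairs[ord, , drop = FALSE]
  w <- w[ord]
  keep <- w <= max_steps
  pairs <- pairs[keep, , drop = FALSE]
  w <- w[keep]
  edges <- list()
  for (wt in unique(w)) {
    at <- which(w == wt)
    # test all edges of this weight against the components formed by
    # strictly shorter edges, before merging any of them
    chosen <- at[vapply(at, function(k) {
      find(pairs[k, 1]) != find(pairs[k, 2])
    }, logical(1))]
    for (k in chosen) {
      edges[[length(edges) + 1]] <- c(pairs[k, 1], pairs[k, 2], wt)
      ri <- find(pairs[k, 1])
      rj <- find(pairs[k, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  if (length(edges) == 0) {
    return(tibble(from = integer(), to = integer(), steps = integer()))
  }
  m <- do.call(rbind, edges)
  tibble(from = m[, 1], to = m[, 2], steps = as.integer(m[, 3]))
}

#' Build a minimum spanning haplotype network
#'
#' Computes pairwise Hamming distances (pairwise deletion) between
#' aligned haplotypes, takes the union of all minimum spanning trees, and
#' expands every k-step edge into k unit edges through k-1 inferred
#' median nodes. Observed nodes carry frequencies and optional per-group
#' counts (e.g. geographic macroregions).
#'
#' @param haplotypes Tibble `haplotype_id, sequence` with optional
#'   `frequency` (default 1 per haplotype).
#' @param groups Optional tibble `haplotype_id, group, count` of
#'   free-form node annotations.
#' @param max_steps Optional connection limit: pairs farther than this
#'   are never joined directly (default unlimited, giving a connected
#'   network).
#' @return An object of class `haplotype_network`: `nodes` (including
#'   medians), `edges` (original multi-step MSN edges), `unit_edges`
#'   (after median insertion), `groups`, and an igraph `graph` of the
#'   unit-edge network. `tidy()` returns the edges, `glance()` a one-row
#'   summary.
#' @export
build_haplotype_network <- function(haplotypes, groups = NULL,
                                    max_steps = Inf) {
  stopifnot(nrow(haplotypes) >= 1,
            !anyDuplicated(haplotypes$haplotype_id))
  if (length(unique(nchar(haplotypes$sequence))) != 1) {
    abort("Haplotypes must be aligned to equal length.")
  }
  if (!"frequency" %in% names(haplotypes)) {
    haplotypes$frequency <- 1
  }
  d <- hamming_matrix(haplotypes$sequence)
  edges <- msn_edges(d, max_steps)
  edges <- mutate(edges,
                  from = haplotypes$haplotype_id[.data$from],
                  to = haplotypes$haplotype_id[.data$to])
  # expand multi-step edges through median nodes
  medians <- character()
  unit <- list()
  med_i <- 0
  for (k in seq_len(nrow(edges))) {
    steps <- edges$steps[k]
    chain <- edges$from[k]
    if (steps > 1) {
      for (s in seq_len(steps - 1)) {
        med_i <- med_i + 1
        chain <- c(chain, sprintf("median_%d", med_i))
      }
    }
    chain <- c(chain, edges$to[k])
    medians <- c(medians, chain[-c(1, length(chain))])
    unit[[k]] <- tibble(from = head(chain, -1), to = tail(chain, -1))
  }
  unit_edges <- if (length(unit)) {
    list_rbind(unit)
  } else {
    tibble(from = character(), to = character())
  }
  nodes <- bind_rows(
    tibble(id = haplotypes$haplotype_id,
           frequency = haplotypes$frequency, median = FALSE),
    tibble(id = medians, frequency = 0, median = TRUE)
  )
  graph <- igraph::graph_from_data_frame(
    unit_edges, directed = FALSE, vertices = nodes
  )
  structure(
    list(nodes = nodes, edges = edges, unit_edges = unit_edges,
         groups = groups, graph = graph,
         distances = d, haplotype_ids = haplotypes$haplotype_id),
    class = "haplotype_network"
  )
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", sum(!x$nodes$median), " haplotypes, ",
      sum(x$nodes$median), " inferred medians, ", nrow(x$edges),
      " connections\n", sep = "")
  invisible(x)
}

#' @rdname build_haplotype_network
#' @param x A `haplotype_network`.
#' @param ... Unused.
#' @method tidy haplotype_network
#' @export
tidy.haplotype_network <- function(x, ...) as_tibble(x$edges)

#' @rdname build_haplotype_network
#' @method glance haplotype_network
#' @export
glance.haplotype_network <- function(x, ...) {
  tibble(
    n_haplotypes = sum(!x$nodes$median),
    n_medians = sum(x$nodes$median),
    n_edges = nrow(x$edges),
    connected = igraph::is_connected(x$graph)
  )
}

#' Export a haplotype network as GraphML
#'
#' @param network A [build_haplotype_network()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' Network path length between two observed haplotypes
#'
#' Shortest path in unit-edge steps; never below the Hamming distance,
#' with equality when the network connects the pair directly.
#'
#' @param network A `haplotype_network`.
#' @param a,b Haplotype ids.
#' @return Integer number of mutational steps (Inf if disconnected).
#' @export
network_steps <- function(network, a, b) {
  as.numeric(igraph::distances(network$graph, v = a, to = b))
}
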