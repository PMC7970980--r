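# Distance-based lineage assignment, the minimum spanning haplotype
# network against exhaustive spanning-tree enumeration, and the max
# chi-square recombination scanner.

test_that("p_distance counts mismatches with pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT"),
               list(n_diff = 0L, n_compared = 4L, p_dist = 0))
  set.seed(101)
  a <- random_sequence(630)
  b <- mutate_sequence(a, 6)
  d <- p_distance(a, b)
  expect_equal(d$n_diff, 6)
  expect_equal(round(100 * d$p_dist, 2), 0.95)

  c622 <- random_sequence(622)
  d622 <- p_distance(c622, mutate_sequence(c622, 31))
  expect_equal(round(100 * d622$p_dist, 1), 5.0)

  # gapped columns are excluded from the comparison
  g <- p_distance("AC-TA", "ACGTT")
  expect_equal(g$n_compared, 4)
  expect_equal(g$n_diff, 1)
  expect_error(p_distance("ACGT", "ACG"), "equal length")
})

test_that("p_distance is a pseudometric on random triples", {
  set.seed(102)
  for (k in 1:30) {
    base <- random_sequence(120)
    x <- mutate_sequence(base, sample(0:20, 1))
    y <- mutate_sequence(base, sample(0:20, 1))
    z <- mutate_sequence(base, sample(0:20, 1))
    dxy <- p_distance(x, y)$n_diff
    dyx <- p_distance(y, x)$n_diff
    expect_equal(dxy, dyx)
    expect_equal(p_distance(x, x)$n_diff, 0)
    expect_lte(dxy, p_distance(x, z)$n_diff + p_distance(z, y)$n_diff)
  }
})

test_that("assign_lineage picks the nearest reference and flags ties", {
  panel <- demo_reference_panel()
  seqs <- demo_allele_sequences()
  g <- seqs$sequence[seqs$locus == "EF1a" & seqs$allele == "G"]
  call_g <- assign_lineage(g, panel, "EF1a", allele_name = "G")
  expect_equal(call_g$best_lineage, "BTN2")
  expect_equal(call_g$n_diff, 0)
  expect_false(call_g$novel)

  # built 6 substitutions from the BTN2 COI reference, far from BTN1
  set.seed(111)
  coi_b <- panel$sequence[panel$lineage == "BTN2" & panel$locus == "COI"]
  q <- mutate_sequence(coi_b, 6)
  call_q <- assign_lineage(q, panel, "COI")
  expect_equal(call_q$best_lineage, "BTN2")
  expect_equal(call_q$n_diff, 6)

  # an equidistant query is reported ambiguous, not broken arbitrarily
  p2 <- tibble::tibble(
    lineage = c("L1", "L2"), locus = "X",
    allele_name = c("a", "b"),
    sequence = c("AAAAAAAAAA", "CCAAAAAAAA")
  )
  tie <- assign_lineage("ACAAAAAAAA", p2, "X")
  expect_true(tie$ambiguous)
  expect_equal(tie$best_lineage, "ambiguous")
  expect_error(assign_lineage(g, panel, "nope"), "no entries")
})

test_that("lineage assignment recovers the generating lineage", {
  panel <- demo_reference_panel()
  set.seed(112)
  for (k in 1:20) {
    entry <- panel[sample(nrow(panel), 1), ]
    q <- mutate_sequence(entry$sequence, sample(0:5, 1))
    others <- dplyr::filter(panel, locus == entry$locus,
                            lineage != entry$lineage)
    if (nrow(others) == 0) next
    d_others <- min(vapply(others$sequence, function(s)
      p_distance(q, s)$n_diff, numeric(1)))
    d_own <- p_distance(q, entry$sequence)$n_diff
    if (d_others < 3 * max(d_own, 1)) next  # ensure the margin holds
    call <- assign_lineage(q, panel, entry$locus)
    expect_equal(call$best_lineage, entry$lineage)
  }
})

test_that("the haplotype network equals the union of all MSTs", {
  # single haplotype
  net1 <- build_haplotype_network(
    tibble::tibble(haplotype_id = "A", sequence = "ACGT"))
  expect_equal(nrow(net1$edges), 0)
  expect_equal(nrow(net1$nodes), 1)

  # star: d(A,B) = d(A,C) = 1, d(B,C) = 2
  star <- build_haplotype_network(tibble::tibble(
    haplotype_id = c("A", "B", "C"),
    sequence = c("AAAA", "AAAT", "AAGA")
  ))
  expect_equal(nrow(star$edges), 2)
  expect_setequal(star$edges$to[star$edges$from == "A"], c("B", "C"))
  expect_true(all(star$edges$steps == 1))

  # rectangle with two alternative MSTs: both diagonals' alternatives kept
  rect <- tibble::tibble(
    haplotype_id = c("P", "Q", "R", "S"),
    sequence = c("AAAAAA", "TTAAAA", "AAATTA", "TTATTA")
  )
  net <- build_haplotype_network(rect)
  expect_equal(nrow(net$edges), 4)

  # against exhaustive spanning-tree enumeration on random sets
  set.seed(121)
  for (k in 1:8) {
    n <- sample(3:6, 1)
    base <- random_sequence(30)
    haps <- tibble::tibble(
      haplotype_id = paste0("H", seq_len(n)),
      sequence = vapply(seq_len(n), function(i)
        mutate_sequence(base, sample(0:6, 1)), character(1))
    )
    haps <- haps[!duplicated(haps$sequence), ]
    if (nrow(haps) < 2) next
    d <- outer(seq_len(nrow(haps)), seq_len(nrow(haps)),
               Vectorize(function(i, j)
                 p_distance(haps$sequence[i], haps$sequence[j])$n_diff))
    oracle <- enumerate_msn_edges(d)
    net_k <- build_haplotype_network(haps)
    got <- t(apply(cbind(
      match(net_k$edges$from, haps$haplotype_id),
      match(net_k$edges$to, haps$haplotype_id)
    ), 1, sort))
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(oracle))
  }
})

test_that("network path length is bounded below by the Hamming distance", {
  set.seed(122)
  base <- random_sequence(40)
  haps <- tibble::tibble(
    haplotype_id = paste0("H", 1:5),
    sequence = c(base, vapply(1:4, function(i)
      mutate_sequence(base, i + 1), character(1)))
  )
  net <- build_haplotype_network(haps)
  for (i in 1:4) for (j in (i + 1):5) {
    hd <- p_distance(haps$sequence[i], haps$sequence[j])$n_diff
    steps <- network_steps(net, haps$haplotype_id[i],
                           haps$haplotype_id[j])
    expect_gte(steps, hd)
  }
  # a direct MSN edge realizes the Hamming distance exactly
  e1 <- net$edges[1, ]
  hd1 <- p_distance(
    haps$sequence[match(e1$from, haps$haplotype_id)],
    haps$sequence[match(e1$to, haps$haplotype_id)]
  )$n_diff
  expect_equal(network_steps(net, e1$from, e1$to), hd1)
  expect_equal(e1$steps, hd1)
})

test_that("median insertion yields unit edges and GraphML export works", {
  haps <- tibble::tibble(
    haplotype_id = c("A", "B"), sequence = c("AAAA", "TTTA")
  )
  net <- build_haplotype_network(haps)
  expect_equal(net$edges$steps, 3)
  expect_equal(sum(net$nodes$median), 2)
  expect_equal(nrow(net$unit_edges), 3)
  expect_true(igraph::is_connected(net$graph))
  f <- tempfile(fileext = ".graphml")
  write_graphml(net, f)
  expect_true(file.size(f) > 0)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g2), 4)
})

test_that("recombination breakpoints are recovered near the truth", {
  set.seed(131)
  f <- random_sequence(622)
  m <- mutate_sequence(f, 31)  # ~5% divergent parents
  q <- make_recombinant_cr(f, m, c(200, 400))
  sc <- scan_recombination(q, f, m, window = 50)
  expect_equal(length(sc$breakpoints), 2)
  expect_lt(abs(sc$breakpoints[1] - 200), 25)
  expect_lt(abs(sc$breakpoints[2] - 400), 25)
  expect_equal(sc$segments$parent, c("A", "B", "A"))
  # segments tile the alignment
  expect_equal(sc$segments$start[1], 0)
  expect_equal(sc$segments$end[nrow(sc$segments)], 622)
  expect_true(all(sc$segments$start[-1] ==
                    sc$segments$end[-nrow(sc$segments)]))

  # no breakpoints when the query is one of the parents
  expect_equal(length(scan_recombination(f, f, m, 50)$breakpoints), 0)

  # two recombinants built on the same interval report identical
  # breakpoints
  q2 <- make_recombinant_cr(f, m, c(200, 400))
  sc2 <- scan_recombination(q2, f, m, window = 50)
  expect_identical(sc$breakpoints, sc2$breakpoints)
  expect_error(scan_recombination(q, f, m, window = 700), "exceeds")
  expect_error(scan_recombination(q, substr(f, 1, 10), m, 50), "aligned")
})

test_that("mean breakpoint error stays within half a window", {
  set.seed(132)
  errs <- c()
  for (k in 1:100) {
    L <- 622
    div <- sample(19:37, 1)  # 3-6% divergence
    f <- random_sequence(L)
    m <- mutate_sequence(f, div)
    b1 <- sample(120:260, 1)
    b2 <- sample(360:500, 1)
    q <- make_recombinant_cr(f, m, c(b1, b2))
    sc <- scan_recombination(q, f, m, window = 50)
    if (length(sc$breakpoints) == 0) {
      # an uninformative draw (no parental difference inside the
      # segment); count as a full-window miss
      errs <- c(errs, 50, 50)
      next
    }
    errs <- c(errs,
              min(abs(sc$breakpoints - b1)),
              min(abs(sc$breakpoints - b2)))
  }
  expect_lte(mean(errs), 25)
})
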