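# Lineage assignment: nearest-reference classification of cancer alleles
# against a BTN1/BTN2/host panel using uncorrected p-distances with
# pairwise deletion of gapped columns.

#' Assign an allele to its nearest reference lineage
#'
#' Computes p-distances from `sequence` to every panel entry for `locus`
#' and reports the lineage of the closest reference. Ties between
#' different lineages at the minimum distance are reported as
#' `"ambiguous"` rather than broken arbitrarily. The call is flagged
#' `novel` when even the best reference is farther than
#' `novel_threshold`.
#'
#' @param sequence Query allele sequence (aligned to the panel).
#' @param panel Reference panel tibble `lineage, locus, allele_name,
#'   sequence` (see [read_reference_panel()]).
#' @param locus Locus to compare within.
#' @param novel_threshold p-distance above which the allele is called
#'   novel.
#' @param allele_name Optional query name carried into the result.
#' @return A one-row tibble `allele, locus, best_lineage, best_allele,
#'   n_diff, p_dist, novel, ambiguous`.
#' @export
assign_lineage <- function(sequence, panel, locus,
                           novel_threshold = 0.03,
                           allele_name = NA_character_) {
  loc <- locus
  entries <- filter(panel, .data$locus == loc)
  if (nrow(entries) == 0) {
    abort(sprintf("Reference panel has no entries for locus %s.", loc))
  }
  d <- map(entries$sequence, ~ p_distance(sequence, .x))
  n_diff <- map_int(d, ~ as.integer(.x$n_diff))
  p_dist <- map_dbl(d, "p_dist")
  best <- which(n_diff == min(n_diff))
  lineages <- unique(entries$lineage[best])
  ambiguous <- length(lineages) > 1
  best_n_diff <- n_diff[best[[1]]]
  best_p_dist <- p_dist[best[[1]]]
  tibble(
    allele = allele_name,
    locus = loc,
    best_lineage = if (ambiguous) "ambiguous" else lineages,
    best_allele = entries$allele_name[best[[1]]],
    n_diff = best_n_diff,
    p_dist = best_p_dist,
    novel = best_p_dist > novel_threshold,
    ambiguous = ambiguous
  )
}

#' Assign many alleles at once
#'
#' @param alleles Tibble `allele, locus, sequence`.
#' @inheritParams assign_lineage
#' @return Row-bound [assign_lineage()] results.
#' @export
assign_lineages <- function(alleles, panel, novel_threshold = 0.03) {
  list_rbind(pmap(
    list(alleles$sequence, alleles$locus, alleles$allele),
    function(s, loc, nm) {
      assign_lineage(s, panel, loc, novel_threshold, allele_name = nm)
    }
  ))
}
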