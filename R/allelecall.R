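# Allele calling from molecular-cloning colony sequences and mixed
# chromatogram signals. Implements the artifact rules used in colony-based
# BTN genotyping: sequences seen in a single colony are PCR/cloning
# artifacts and are excluded, unless the identical sequence recurs in
# another cloning experiment of the study (singleton rescue); frequencies
# are computed over the retained ("major-sequence") colonies only.

#' Call alleles from a cloning experiment
#'
#' Groups identical colony sequences. A group with fewer than
#' `min_colonies` colonies is excluded as an artifact unless the identical
#' sequence occurs in `cross_reference` (another tissue or individual of
#' the study); rescued singletons are retained with status `"rare"`.
#' Frequencies are computed over retained colonies only.
#'
#' @param clone_set Tibble `colony_id, sequence` (plus optional
#'   `individual_id, locus, tissue` carried through), one row per colony.
#' @param cross_reference Optional tibble of colonies (or alleles) from
#'   other cloning experiments, with a `sequence` column; used for the
#'   singleton rescue rule.
#' @param min_colonies Minimum colony count for unconditional retention.
#' @param rescue Set to `FALSE` to disable the rescue rule (plain
#'   singleton exclusion).
#' @param known_alleles Optional tibble `allele, sequence`: sequences
#'   matching a known allele inherit its name; novel sequences get
#'   sequential numeric ids per locus.
#' @return A tissue-genotype tibble: `individual_id, locus, tissue,
#'   allele, sequence, colony_count, frequency, status` with status in
#'   `common`/`rare`/`artifact_excluded`. Excluded calls carry frequency 0.
#' @export
call_alleles <- function(clone_set, cross_reference = NULL,
                         min_colonies = 2, rescue = TRUE,
                         known_alleles = NULL) {
  if (nrow(clone_set) == 0) abort("Empty clone set.")
  groups <- count(clone_set, .data$sequence, name = "colony_count")
  groups <- arrange(groups, desc(.data$colony_count), .data$sequence)
  rescued <- if (rescue && !is.null(cross_reference)) {
    groups$sequence %in% cross_reference$sequence
  } else {
    rep(FALSE, nrow(groups))
  }
  groups$status <- ifelse(
    groups$colony_count >= min_colonies, "common",
    ifelse(rescued, "rare", "artifact_excluded")
  )
  retained <- groups$status != "artifact_excluded"
  if (!any(retained)) {
    abort("All colonies excluded as artifacts: no allele can be called.")
  }
  n_major <- sum(groups$colony_count[retained])
  groups$frequency <- ifelse(retained,
                             groups$colony_count / n_major, 0)
  locus <- if ("locus" %in% names(clone_set)) {
    clone_set$locus[[1]]
  } else "allele"
  groups$allele <- name_alleles(groups, locus, known_alleles)
  out <- tibble(
    individual_id = if ("individual_id" %in% names(clone_set)) {
      clone_set$individual_id[[1]]
    } else NA_character_,
    locus = locus,
    tissue = if ("tissue" %in% names(clone_set)) {
      clone_set$tissue[[1]]
    } else NA_character_,
    allele = groups$allele,
    sequence = groups$sequence,
    colony_count = groups$colony_count,
    frequency = groups$frequency,
    status = groups$status
  )
  attr(out, "n_major") <- n_major
  attr(out, "n_total") <- nrow(clone_set)
  out
}

# Known sequences inherit their panel name; novel sequences get sequential
# numerals per locus, most supported first.
name_alleles <- function(groups, locus, known_alleles) {
  nm <- rep(NA_character_, nrow(groups))
  if (!is.null(known_alleles)) {
    idx <- match(groups$sequence, known_alleles$sequence)
    nm[!is.na(idx)] <- known_alleles$allele[idx[!is.na(idx)]]
  }
  novel <- which(is.na(nm))
  nm[novel] <- paste0(locus, "-", seq_along(novel))
  nm
}

# Positions inside or immediately adjacent to a homopolymer run of at
# least `min_run` identical bases, in either sequence of the pair.
homopolymer_positions <- function(sequence, min_run) {
  r <- rle(seq_chars(sequence))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$lengths >= min_run
  pos <- integer()
  for (k in which(keep)) {
    pos <- c(pos, (starts[k] - 1):(ends[k] + 1))
  }
  pos[pos >= 1 & pos <= nchar(sequence)]
}

#' Merge homopolymer-adjacent allele variants
#'
#' Polymerase slippage at long homopolymer runs creates spurious variants
#' differing by a single substitution inside or flanking the run. When
#' enabled, allele pairs of equal length differing at exactly one such
#' position are merged into the higher-count allele, counts summed and
#' frequencies renormalized.
#'
#' @param genotype Tissue-genotype tibble from [call_alleles()].
#' @param min_run Minimum homopolymer run length (default 6).
#' @param enabled Set `FALSE` to return the genotype unchanged.
#' @return The (possibly merged) genotype tibble.
#' @export
merge_homopolymer_variants <- function(genotype, min_run = 6,
                                       enabled = TRUE) {
  if (!enabled) return(genotype)
  repeat {
    live <- which(genotype$status != "artifact_excluded")
    merged <- FALSE
    for (i in live) {
      for (j in live) {
        if (j <= i) next
        a <- genotype$sequence[i]
        b <- genotype$sequence[j]
        if (nchar(a) != nchar(b)) next
        diff_pos <- which(seq_chars(a) != seq_chars(b))
        if (length(diff_pos) != 1) next
        hp <- union(homopolymer_positions(a, min_run),
                    homopolymer_positions(b, min_run))
        if (!diff_pos %in% hp) next
        win <- if (genotype$colony_count[i] >= genotype$colony_count[j]) {
          i
        } else j
        lose <- setdiff(c(i, j), win)
        genotype$colony_count[win] <- genotype$colony_count[win] +
          genotype$colony_count[lose]
        genotype <- genotype[-lose, , drop = FALSE]
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  keep <- genotype$status != "artifact_excluded"
  genotype$frequency[keep] <- genotype$colony_count[keep] /
    sum(genotype$colony_count[keep])
  arrange(genotype, desc(.data$colony_count), .data$allele)
}

#' Resolve overlapping chromatogram peaks into two templates
#'
#' Reconstructs the dominant and minority sequences from per-site
#' major/minor base calls ("piggyback" peaks). In a hemolymph context the
#' dominant sequence is attributed to the presumable cancer allele and the
#' minority to the host -- but only when the minority sequence equals the
#' independently determined foot allele of the same individual; otherwise
#' both are left unattributed.
#'
#' @param site_calls Tibble `position, major_base, minor_base` covering
#'   the full locus (`minor_base` `NA` at clean sites), as produced by
#'   [simulate_chromatogram()].
#' @param foot_allele Foot-tissue sequence of the same individual, or
#'   `NULL`.
#' @param max_mixed_fraction Above this fraction of mixed sites the
#'   major/minor assignment is unreliable and an error is raised.
#' @return A list `dominant, minority, n_mixed, attribution` where
#'   `attribution` is a named character vector over the two sequences
#'   (`cancer-candidate`/`host-candidate`, `unattributed`, or `none` when
#'   there are no mixed sites).
#' @export
resolve_piggyback <- function(site_calls, foot_allele = NULL,
                              max_mixed_fraction = 0.3) {
  stopifnot(all(c("position", "major_base", "minor_base") %in%
                  names(site_calls)))
  site_calls <- arrange(site_calls, .data$position)
  mixed <- !is.na(site_calls$minor_base)
  if (mean(mixed) > max_mixed_fraction) {
    abort("Unresolvable mixture: too many mixed chromatogram sites.")
  }
  dominant <- chars_seq(site_calls$major_base)
  minority_chars <- site_calls$major_base
  minority_chars[mixed] <- site_calls$minor_base[mixed]
  minority <- chars_seq(minority_chars)
  attribution <- if (!any(mixed)) {
    c(dominant = "none", minority = "none")
  } else if (!is.null(foot_allele) && identical(minority, foot_allele)) {
    c(dominant = "cancer-candidate", minority = "host-candidate")
  } else {
    c(dominant = "unattributed", minority = "unattributed")
  }
  list(dominant = dominant, minority = minority,
       n_mixed = sum(mixed), attribution = attribution)
}

#' Compare microsatellite fragment profiles between tissues
#'
#' Flags fragment sizes whose peak-height share in the hemolymph exceeds
#' their share in the foot by at least `enrichment_ratio`. Fragment
#' enrichment alone cannot distinguish a cancer-derived fragment from a
#' host fragment shared across individuals, so results carry an
#' `"inconclusive"` evidence grade.
#'
#' @param hemolymph,foot Tibbles `size, height` (fragment length in bp,
#'   electropherogram peak height).
#' @param enrichment_ratio Minimum hemolymph/foot share ratio.
#' @return A tibble of enriched sizes with both shares and the ratio
#'   (infinite when the fragment is absent from the foot); attribute
#'   `evidence_grade` is `"inconclusive"`.
#' @export
compare_fragment_profiles <- function(hemolymph, foot,
                                      enrichment_ratio = 2) {
  if (nrow(hemolymph) == 0 || nrow(foot) == 0 ||
      sum(hemolymph$height) == 0 || sum(foot$height) == 0) {
    abort("Empty fragment profile.")
  }
  h <- mutate(hemolymph, hemolymph_share = .data$height /
                sum(.data$height))
  f <- mutate(foot, foot_share = .data$height / sum(.data$height))
  joined <- full_join(select(h, "size", "hemolymph_share"),
                      select(f, "size", "foot_share"), by = "size")
  joined <- mutate(joined,
                   hemolymph_share = dplyr::coalesce(.data$hemolymph_share, 0),
                   foot_share = dplyr::coalesce(.data$foot_share, 0),
                   ratio = .data$hemolymph_share / .data$foot_share)
  out <- filter(joined, .data$hemolymph_share > 0,
                .data$ratio >= enrichment_ratio)
  out <- arrange(out, .data$size)
  attr(out, "evidence_grade") <- "inconclusive"
  out
}
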