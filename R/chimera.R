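# Chimerism detection and BTN calling. An individual is genetically
# chimeric when its hemolymph is enriched for alleles its foot does not
# carry (or carries at lower frequency). BTN requires two kinds of
# evidence: chimerism, and identity of the "extra" hemolymph alleles with
# the cancer genotype shared across diseased individuals.

retained_rows <- function(genotype) {
  if ("status" %in% names(genotype)) {
    filter(genotype, .data$status != "artifact_excluded")
  } else {
    genotype
  }
}

#' Hemolymph-enriched ("extra") alleles at one locus
#'
#' Returns alleles whose hemolymph frequency exceeds their foot frequency
#' by more than `margin` (strictly); an allele absent from the foot counts
#' as frequency 0 there. Alleles are matched across tissues by sequence
#' identity.
#'
#' @param hemolymph,foot Tissue-genotype tibbles for the same individual
#'   and locus (artifact-excluded rows are ignored).
#' @param margin Enrichment margin; the default 0 demands strict
#'   hemolymph dominance, a positive value absorbs cloning noise.
#' @return A tibble `allele, sequence, freq_hemolymph, freq_foot`.
#' @export
extra_alleles <- function(hemolymph, foot, margin = 0) {
  if (is.null(hemolymph) || nrow(hemolymph) == 0) {
    abort("Missing hemolymph genotype.")
  }
  if (is.null(foot) || nrow(foot) == 0) {
    abort("Missing foot genotype.")
  }
  h <- retained_rows(hemolymph)
  f <- retained_rows(foot)
  joined <- left_join(
    select(h, "allele", "sequence", freq_hemolymph = "frequency"),
    select(f, "sequence", freq_foot = "frequency"),
    by = "sequence"
  )
  joined <- mutate(joined,
                   freq_foot = dplyr::coalesce(.data$freq_foot, 0))
  filter(joined, .data$freq_hemolymph - .data$freq_foot > margin)
}

#' Detect genetic chimerism from paired-tissue genotypes
#'
#' Applies [extra_alleles()] to every individual x locus with both a
#' hemolymph and a foot genotype. An individual is chimeric when at least
#' one locus yields a nonempty extra-allele set.
#'
#' @param genotypes Long genotype tibble (`individual_id, locus, tissue,
#'   allele, sequence, frequency`, optional `status`) covering both
#'   tissues.
#' @param margin See [extra_alleles()].
#' @return An object of class `chimerism_result`: `extras` (per
#'   individual/locus enriched alleles) and `individuals`
#'   (`individual_id, chimeric, n_extra`). `tidy()` returns the extras,
#'   `glance()` the per-individual summary.
#' @export
detect_chimerism <- function(genotypes, margin = 0) {
  ids <- unique(genotypes$individual_id)
  extras <- list()
  individuals <- list()
  for (id in ids) {
    g <- filter(genotypes, .data$individual_id == id)
    loci <- intersect(
      unique(g$locus[g$tissue == "hemolymph"]),
      unique(g$locus[g$tissue == "foot"])
    )
    if (length(loci) == 0) {
      abort(sprintf(
        "Individual %s lacks paired hemolymph/foot genotypes.", id))
    }
    ex <- list_rbind(map(loci, function(loc) {
      e <- extra_alleles(
        filter(g, .data$locus == loc, .data$tissue == "hemolymph"),
        filter(g, .data$locus == loc, .data$tissue == "foot"),
        margin = margin
      )
      if (nrow(e) == 0) return(NULL)
      mutate(e, individual_id = id, locus = loc, .before = 1)
    }))
    n_extra <- if (is.null(ex)) 0L else nrow(ex)
    extras[[length(extras) + 1]] <- ex
    individuals[[length(individuals) + 1]] <- tibble(
      individual_id = id, chimeric = n_extra > 0, n_extra = n_extra
    )
  }
  structure(
    list(
      extras = list_rbind(extras) %||%
        tibble(individual_id = character(), locus = character(),
               allele = character(), sequence = character(),
               freq_hemolymph = numeric(), freq_foot = numeric()),
      individuals = list_rbind(individuals)
    ),
    class = "chimerism_result"
  )
}

#' @export
print.chimerism_result <- function(x, ...) {
  cat("<chimerism_result> ", sum(x$individuals$chimeric), " of ",
      nrow(x$individuals), " individuals chimeric\n", sep = "")
  print(x$individuals)
  invisible(x)
}

#' @rdname detect_chimerism
#' @param x A `chimerism_result`.
#' @param ... Unused.
#' @method tidy chimerism_result
#' @export
tidy.chimerism_result <- function(x, ...) as_tibble(x$extras)

#' @rdname detect_chimerism
#' @method glance chimerism_result
#' @export
glance.chimerism_result <- function(x, ...) {
  tibble(n_individuals = nrow(x$individuals),
         n_chimeric = sum(x$individuals$chimeric))
}

#' Cancer genotype shared across diseased individuals
#'
#' Extra alleles recurring (by sequence identity) in at least
#' `min_support` chimeric individuals form the inferred cancer genotype.
#' The default support is every chimeric individual -- universality is the
#' evidence -- relaxed to `ceiling(N / 2)` when six or more individuals
#' are available.
#'
#' @param chimerism A [detect_chimerism()] result.
#' @param locus Optional locus filter (default: all loci, reported per
#'   locus).
#' @param min_support Minimum number of supporting individuals.
#' @return A tibble `locus, allele, sequence, support` ranked by support,
#'   of class `cancer_genotype`. More than two nuclear alleles is flagged
#'   with a warning (a diploid clone is expected), not rejected.
#' @export
shared_cancer_alleles <- function(chimerism, locus = NULL,
                                  min_support = NULL) {
  stopifnot(inherits(chimerism, "chimerism_result"))
  n_chim <- sum(chimerism$individuals$chimeric)
  if (n_chim < 2) {
    abort("At least two chimeric individuals are required.")
  }
  if (is.null(min_support)) {
    min_support <- if (n_chim >= 6) ceiling(n_chim / 2) else n_chim
  }
  ex <- chimerism$extras
  if (!is.null(locus)) {
    locus_filter <- locus
    ex <- filter(ex, .data$locus %in% locus_filter)
  }
  shared <- summarise(
    group_by(ex, .data$locus, .data$sequence),
    allele = .data$allele[[1]],
    support = n_distinct(.data$individual_id),
    .groups = "drop"
  )
  shared <- filter(shared, .data$support >= min_support)
  shared <- arrange(shared, desc(.data$support), .data$locus,
                    .data$allele)
  shared <- select(shared, "locus", "allele", "sequence", "support")
  if (nrow(shared) == 0) {
    warn("No allele is shared at the requested support: empty genotype.")
  }
  n_nuclear <- sum(shared$locus == "EF1a")
  if (n_nuclear > 2) {
    warn(sprintf(
      "%d shared EF1a alleles; a diploid clone is expected to carry 2.",
      n_nuclear))
  }
  class(shared) <- c("cancer_genotype", class(shared))
  attr(shared, "min_support") <- min_support
  shared
}

#' Two-evidence BTN call
#'
#' An individual is BTN-positive when it is chimeric AND the extra alleles
#' of at least `match_min` loci intersect the shared cancer genotype (by
#' sequence identity). A chimeric individual with only novel extras is
#' negative with a `possible-new-lineage` annotation.
#'
#' @param chimerism A [detect_chimerism()] result.
#' @param cancer_genotype A [shared_cancer_alleles()] result (must be
#'   nonempty).
#' @param match_min Minimum number of matching loci.
#' @return A tibble `individual_id, chimeric, matched_loci, positive,
#'   note`.
#' @export
call_btn <- function(chimerism, cancer_genotype, match_min = 1) {
  stopifnot(inherits(chimerism, "chimerism_result"))
  if (nrow(cancer_genotype) == 0) {
    abort("Empty cancer genotype: nothing to match against.")
  }
  per_ind <- map(seq_len(nrow(chimerism$individuals)), function(i) {
    id <- chimerism$individuals$individual_id[i]
    chim <- chimerism$individuals$chimeric[i]
    ex <- filter(chimerism$extras, .data$individual_id == id)
    hits <- filter(ex, .data$sequence %in% cancer_genotype$sequence)
    matched_loci <- n_distinct(hits$locus)
    positive <- chim && matched_loci >= match_min
    tibble(
      individual_id = id, chimeric = chim,
      matched_loci = matched_loci, positive = positive,
      note = if (chim && matched_loci == 0) {
        "possible-new-lineage"
      } else NA_character_
    )
  })
  list_rbind(per_ind)
}

#' Mitochondrial sexing from mantle 16S genotypes
#'
#' Under doubly uniparental inheritance, females are homoplasmic for
#' F-mtDNA while males additionally carry M-mtDNA in the gonad (sampled
#' with the mantle). A specimen is male iff any mantle 16S allele
#' classifies as M-type: within `max_m_distance` (p-distance) of an
#' M-mtDNA reference, or -- when F references are supplied -- closer to
#' the M panel than to the F panel.
#'
#' @param mantle_genotype Mantle 16S genotype tibble (`sequence` column;
#'   artifact-excluded rows ignored).
#' @param m_references Character vector (or tibble with `sequence`) of
#'   M-mtDNA 16S references.
#' @param f_references Optional F-mtDNA references for nearest-panel
#'   classification.
#' @param max_m_distance p-distance threshold for M-type membership.
#' @return `"male"` or `"female"`.
#' @export
mito_sex <- function(mantle_genotype, m_references, f_references = NULL,
                     max_m_distance = 0.05) {
  g <- retained_rows(mantle_genotype)
  if (nrow(g) == 0) abort("Empty mantle genotype.")
  as_seqs <- function(x) if (is.data.frame(x)) x$sequence else x
  m_refs <- as_seqs(m_references)
  f_refs <- as_seqs(f_references)
  is_m <- map_lgl(g$sequence, function(s) {
    d_m <- min(map_dbl(m_refs, ~ p_distance(s, .x)$p_dist))
    if (!is.null(f_refs) && length(f_refs) > 0) {
      d_f <- min(map_dbl(f_refs, ~ p_distance(s, .x)$p_dist))
      d_m <= max_m_distance || d_m < d_f
    } else {
      d_m <= max_m_distance
    }
  })
  if (any(is_m)) "male" else "female"
}
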