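# Packaged worked example: a colony-count table from four diseased
# mussels (J54, J111, J161, J181) genotyped at EF1a (hemolymph + foot,
# molecular cloning), the mitochondrial control region CR (hemolymph
# cloning, foot direct sequencing) and COI (direct sequencing with
# piggyback resolution). The counts are real printed values; the allele
# sequences behind them are synthetic stand-ins generated
# deterministically with every divergence the analysis relies on (the
# G/H cancer pair at 21 substitutions, G1 one substitution from G, D and
# 7 separated by a single SNP at a 9-bp poly-A run, COI cancer alleles 6
# substitutions apart, CR cancer alleles 31 apart with recombinant F+M
# structure).

DEMO_SEED <- 20210311

#' Synthetic allele sequences for the packaged worked example
#'
#' Deterministic; the same call always returns the same sequences.
#'
#' @return A tibble `locus, allele, sequence` covering every allele named
#'   in [load_demo_cloning_table()] plus the 16S F/M references.
#' @export
demo_allele_sequences <- function() {
  withr::with_seed(DEMO_SEED, {
    # EF1a ----------------------------------------------------------
    ef_anc <- random_sequence(450)
    ef_g <- mutate_sequence(ef_anc, 5)
    ef_h <- mutate_sequence(ef_g, 21)
    ef_g1 <- mutate_sequence(ef_g, 1)
    # D carries a 9-bp poly-A run at positions 200-208 (1-based); allele
    # 7 differs from D by one SNP at the 5' end of that run.
    ef_d <- seq_chars(mutate_sequence(ef_anc, 10))
    ef_d[199] <- "T"
    ef_d[200:208] <- "A"
    ef_d[209] <- "C"
    ef_d <- chars_seq(ef_d)
    ef_7 <- seq_chars(ef_d)
    ef_7[200] <- "T"
    ef_7 <- chars_seq(ef_7)
    ef_hosts <- setNames(
      map_chr(1:9, ~ mutate_sequence(ef_anc, 10)),
      as.character(1:9)
    )
    ef_hosts[["7"]] <- ef_7
    # COI -----------------------------------------------------------
    coi_anc <- random_sequence(630)
    coi_1 <- mutate_sequence(coi_anc, 15)
    coi_2 <- mutate_sequence(coi_1, 6)
    coi_hosts <- setNames(
      map_chr(3:6, ~ mutate_sequence(coi_anc, .x)),
      as.character(3:6)
    )
    # CR ------------------------------------------------------------
    cr_f <- random_sequence(622)
    cr_m <- mutate_sequence(cr_f, 62)
    cr_1 <- make_recombinant_cr(mutate_sequence(cr_f, 8), cr_m,
                                c(200, 400))
    cr_1p <- mutate_sequence(cr_1, 3)
    cr_2 <- mutate_sequence(cr_1, 31)
    cr_hosts <- setNames(
      map_chr(3:6, ~ mutate_sequence(cr_f, .x)),
      as.character(3:6)
    )
    # 16S -----------------------------------------------------------
    s16_f <- random_sequence(500)
    s16_m <- mutate_sequence(s16_f, 50)

    bind_rows(
      tibble(locus = "EF1a",
             allele = c("D", "G", "G1", "H", names(ef_hosts)),
             sequence = c(ef_d, ef_g, ef_g1, ef_h,
                          unname(ef_hosts))),
      tibble(locus = "COI",
             allele = c("1", "2", names(coi_hosts)),
             sequence = c(coi_1, coi_2, unname(coi_hosts))),
      tibble(locus = "CR",
             allele = c("1", "1p", "2", names(cr_hosts)),
             sequence = c(cr_1, cr_1p, cr_2, unname(cr_hosts))),
      tibble(locus = "16S", allele = c("F", "M"),
             sequence = c(s16_f, s16_m))
    )
  })
}

#' Synthetic reference panel for lineage assignment
#'
#' A stand-in BTN1/BTN2/host panel aligned to the worked-example alleles:
#' the BTN2 entries are the known cancer alleles (EF1a G/H, a COI "B"
#' allele 6 substitutions from COI-1, CR alleles near CR-1/CR-2), BTN1
#' entries are a distant decoy lineage, and host entries carry the F and
#' M mitochondrial ancestors.
#'
#' @return A tibble `lineage, locus, allele_name, sequence`.
#' @export
demo_reference_panel <- function() {
  seqs <- demo_allele_sequences()
  pick <- function(loc, al) {
    seqs$sequence[seqs$locus == loc & seqs$allele == al]
  }
  withr::with_seed(DEMO_SEED + 1, {
    coi_b <- mutate_sequence(pick("COI", "1"), 6)
    cr_d <- mutate_sequence(pick("CR", "1"), 16)
    cr_c <- mutate_sequence(pick("CR", "2"), 5)
    btn1 <- list(
      EF1a = mutate_sequence(pick("EF1a", "G"), 60),
      COI = mutate_sequence(pick("COI", "1"), 40),
      CR = mutate_sequence(pick("CR", "1"), 60)
    )
    host_coi <- mutate_sequence(pick("COI", "3"), 2)
    bind_rows(
      tibble(lineage = "BTN2", locus = "EF1a",
             allele_name = c("G", "H"),
             sequence = c(pick("EF1a", "G"), pick("EF1a", "H"))),
      tibble(lineage = "BTN2", locus = c("COI", "CR", "CR"),
             allele_name = c("B", "D", "C"),
             sequence = c(coi_b, cr_d, cr_c)),
      tibble(lineage = "BTN1", locus = c("EF1a", "COI", "CR"),
             allele_name = paste0("BTN1-", c("EF1a", "COI", "CR")),
             sequence = c(btn1$EF1a, btn1$COI, btn1$CR)),
      tibble(lineage = "host_F", locus = c("COI", "16S"),
             allele_name = c("F-COI", "F-16S"),
             sequence = c(host_coi, pick("16S", "F"))),
      tibble(lineage = "host_M", locus = "16S",
             allele_name = "M-16S", sequence = pick("16S", "M"))
    )
  })
}

#' Load the packaged worked-example cloning table
#'
#' One row per allele per tissue per individual. Cloning rows carry the
#' colony count supporting the allele, the number of colonies with major
#' sequences (`total_major`), the total sequenced (`total_all`, including
#' minor/artifact colonies) and the frequency as printed in the source
#' table. Direct-sequencing rows have no counts; their `signal` column
#' distinguishes the dominant chromatogram sequence from the minority
#' "piggyback" signal.
#'
#' @param path Fixture path (defaults to the installed copy).
#' @return A tibble; structural invariants (counts sum to `total_major`,
#'   `total_major <= total_all`) are checked and violation raises a
#'   packaging error.
#' @export
load_demo_cloning_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cloning_counts.tsv",
                        package = "btnscreen")
  }
  tbl <- readr::read_tsv(
    path, na = ".",
    col_types = readr::cols(
      individual = readr::col_character(),
      locus = readr::col_character(),
      tissue = readr::col_character(),
      method = readr::col_character(),
      allele = readr::col_character(),
      colony_count = readr::col_integer(),
      total_major = readr::col_integer(),
      total_all = readr::col_integer(),
      printed_frequency = readr::col_double(),
      signal = readr::col_character()
    )
  )
  cl <- filter(tbl, .data$method == "cloning")
  chk <- summarise(
    group_by(cl, .data$individual, .data$locus, .data$tissue),
    ok = sum(.data$colony_count) == .data$total_major[[1]] &&
      .data$total_major[[1]] <= .data$total_all[[1]],
    .groups = "drop"
  )
  if (!all(chk$ok)) {
    abort("Packaging error: cloning fixture fails its count invariants.")
  }
  tbl
}

#' Reconstruct colony sets from the packaged cloning table
#'
#' Expands each cloning experiment into one colony row per sequenced
#' clone: `colony_count` copies of each allele's synthetic sequence plus
#' `total_all - total_major` unique single-substitution artifact colonies
#' (each seen once, colliding with no real allele), so the singleton
#' exclusion and rescue rules operate exactly as on real data.
#'
#' @param table A [load_demo_cloning_table()] result.
#' @param sequences Allele sequences, `locus, allele, sequence`.
#' @return A clone-set tibble `individual_id, locus, tissue, colony_id,
#'   sequence`.
#' @export
reconstruct_clone_sets <- function(table = load_demo_cloning_table(),
                                   sequences = demo_allele_sequences()) {
  cl <- filter(table, .data$method == "cloning")
  cl <- left_join(cl, sequences, by = c("locus", "allele"))
  if (anyNA(cl$sequence)) {
    abort("Fixture allele without a packaged sequence.")
  }
  experiments <- distinct(cl, .data$individual, .data$locus,
                          .data$tissue)
  forbidden <- sequences$sequence
  out <- vector("list", nrow(experiments))
  withr::with_seed(DEMO_SEED + 2, {
    for (i in seq_len(nrow(experiments))) {
      e <- experiments[i, ]
      rows <- filter(cl, .data$individual == e$individual,
                     .data$locus == e$locus, .data$tissue == e$tissue)
      seqs <- rep(rows$sequence, rows$colony_count)
      n_art <- rows$total_all[[1]] - rows$total_major[[1]]
      top <- rows$sequence[[which.max(rows$colony_count)]]
      for (a in seq_len(n_art)) {
        repeat {
          cand <- mutate_sequence(top, 1)
          if (!cand %in% forbidden) break
        }
        forbidden <- c(forbidden, cand)
        seqs <- c(seqs, cand)
      }
      out[[i]] <- tibble(
        individual_id = e$individual, locus = e$locus,
        tissue = e$tissue,
        colony_id = sprintf("%s_%s_%s_c%02d", e$individual, e$locus,
                            e$tissue, seq_along(seqs)),
        sequence = seqs
      )
    }
  })
  list_rbind(out)
}

#' Tissue genotypes for the packaged worked example
#'
#' Runs [call_alleles()] (with cross-experiment singleton rescue) on
#' every reconstructed cloning experiment and converts the
#' direct-sequencing rows into genotypes (single allele at frequency 1
#' for clean chromatograms; major/minority mixture left at the printed
#' signal roles for COI hemolymph).
#'
#' @param min_colonies,rescue Passed to [call_alleles()].
#' @return A long genotype tibble across individuals, loci and tissues.
#' @export
demo_genotypes <- function(min_colonies = 2, rescue = TRUE) {
  seqs <- demo_allele_sequences()
  tbl <- load_demo_cloning_table()
  clones <- reconstruct_clone_sets(tbl, seqs)
  known <- select(seqs, "allele", "sequence")
  experiments <- distinct(clones, .data$individual_id, .data$locus,
                          .data$tissue)
  called <- list_rbind(map(seq_len(nrow(experiments)), function(i) {
    e <- experiments[i, ]
    mine <- filter(clones, .data$individual_id == e$individual_id,
                   .data$locus == e$locus, .data$tissue == e$tissue)
    others <- filter(clones, .data$individual_id != e$individual_id |
                       .data$locus != e$locus |
                       .data$tissue != e$tissue)
    call_alleles(mine, cross_reference = others,
                 min_colonies = min_colonies, rescue = rescue,
                 known_alleles = known)
  }))
  direct <- filter(tbl, .data$method == "direct")
  direct <- left_join(direct, seqs, by = c("locus", "allele"))
  direct <- ungroup(mutate(
    group_by(direct, .data$individual, .data$locus, .data$tissue),
    colony_count = NA_integer_,
    frequency = ifelse(.data$signal == "major",
                       1 / sum(.data$signal == "major"), 0),
    status = ifelse(.data$signal == "major", "common", "rare")
  ))
  direct <- rename(direct, individual_id = "individual")
  bind_rows(called, select(direct, names(called)))
}
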