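# Umbrella pipeline: simulate -> flow -> call -> chimera -> lineage ->
# report. Each stochastic stage draws from its own derived seed so the
# whole run is a deterministic function of the configuration.

#' Run the full screening pipeline on a simulated cohort
#'
#' Generates the cohort, screens every specimen by DNA-content flow
#' cytometry, takes the DN-suggested specimens plus `n_controls` healthy
#' controls through molecular-cloning genotyping at EF1a (hemolymph and
#' foot) and CR (hemolymph and foot), detects chimerism, infers the
#' shared cancer genotype, calls BTN, sexes every specimen from its
#' mantle 16S genotype, and (optionally) assigns the cancer alleles to a
#' reference lineage panel.
#'
#' @param config A [sim_config()].
#' @param n_controls Healthy specimens genotyped alongside the
#'   DN-suggested ones.
#' @param min_colonies,merge_homopolymers Allele-calling settings.
#' @param margin Chimerism enrichment margin.
#' @param min_aneuploid_fraction Flow detection floor.
#' @param panel Optional reference panel tibble for lineage assignment.
#' @return An object of class `btn_report`: tibbles `specimens` (one row
#'   per specimen: truth, flow diagnosis, BTN call, inferred sex),
#'   `flow`, `genotypes`, `cancer_genotype`, `btn_calls`,
#'   `lineage_calls`, plus the `chimerism` object and `config`.
#' @export
run_pipeline <- function(config, n_controls = 1, min_colonies = 2,
                         merge_homopolymers = FALSE, margin = 0,
                         min_aneuploid_fraction = 0.05, panel = NULL) {
  cohort <- generate_cohort(config)
  spec <- cohort$specimens

  # flow screening -------------------------------------------------
  flow <- withr::with_seed(config$seed + 1L, {
    list_rbind(map(seq_len(nrow(spec)), function(i) {
      p <- spec$neoplastic_fraction[i]
      ev <- simulate_flow_events(
        p_aneu = p,
        relative_ploidy = if (p > 0) spec$relative_ploidy[i] else 4.5,
        params = config$flow_params, specimen_id = spec$id[i]
      )
      d <- diagnose_ploidy(
        ev, min_aneuploid_fraction = min_aneuploid_fraction
      )
      aneu <- filter(d$peaks, .data$label == "aneuploid")
      tibble(
        id = spec$id[i], dn_status = d$status,
        aneuploid_fraction_est = d$aneuploid_fraction,
        relative_ploidy_est = if (nrow(aneu) > 0) {
          aneu$relative_ploidy[[which.max(aneu$fraction)]]
        } else NA_real_
      )
    }))
  })

  # genotyping of DN-suggested specimens + controls ----------------
  dn_ids <- flow$id[flow$dn_status == "dn_suggested"]
  control_ids <- head(setdiff(
    flow$id[flow$dn_status == "healthy"], dn_ids), n_controls)
  selected <- c(dn_ids, control_ids)

  genotypes <- NULL
  chimerism <- NULL
  cancer_genotype <- empty_cancer_genotype()
  btn_calls <- tibble(individual_id = character(), chimeric = logical(),
                      matched_loci = integer(), positive = logical(),
                      note = character())
  lineage_calls <- NULL

  if (length(selected) > 0) {
    known <- bind_rows(
      select(cohort$clones, "allele", "sequence"),
      distinct(select(cohort$genotypes, "allele", "sequence"))
    )
    known <- distinct(known, .data$sequence, .keep_all = TRUE)
    clone_sets <- withr::with_seed(config$seed + 2L, {
      grid <- tidyr::expand_grid(
        id = selected, locus = c("EF1a", "CR"),
        tissue = c("hemolymph", "foot")
      )
      list_rbind(pmap(grid, function(id, locus, tissue) {
        g <- filter(cohort$genotypes, .data$individual_id == id,
                    .data$locus == !!locus, .data$tissue == !!tissue)
        simulate_cloning(g, n_colonies = config$n_colonies,
                         artifact_rate = config$artifact_rate,
                         avoid = known$sequence)
      }))
    })
    experiments <- distinct(clone_sets, .data$individual_id,
                            .data$locus, .data$tissue)
    genotypes <- list_rbind(map(seq_len(nrow(experiments)),
                                function(i) {
      e <- experiments[i, ]
      mine <- filter(clone_sets, .data$individual_id == e$individual_id,
                     .data$locus == e$locus, .data$tissue == e$tissue)
      others <- filter(clone_sets,
                       .data$individual_id != e$individual_id |
                         .data$locus != e$locus |
                         .data$tissue != e$tissue)
      g <- call_alleles(mine, cross_reference = others,
                        min_colonies = min_colonies,
                        known_alleles = known)
      merge_homopolymer_variants(g, enabled = merge_homopolymers)
    }))

    chimerism <- detect_chimerism(genotypes, margin = margin)
    # the shared cancer genotype is pooled over DN-suggested individuals
    # only: a control that picks up a spurious extra allele through
    # cloning noise must not raise the support bar
    dn_chimerism <- structure(
      list(
        extras = filter(chimerism$extras,
                        .data$individual_id %in% dn_ids),
        individuals = filter(chimerism$individuals,
                             .data$individual_id %in% dn_ids)
      ),
      class = "chimerism_result"
    )
    if (sum(dn_chimerism$individuals$chimeric) >= 2) {
      cancer_genotype <- suppressWarnings(
        shared_cancer_alleles(dn_chimerism)
      )
    }
    btn_calls <- if (nrow(cancer_genotype) > 0) {
      call_btn(chimerism, cancer_genotype)
    } else {
      mutate(chimerism$individuals, matched_loci = 0L,
             positive = FALSE, note = NA_character_,
             .keep = "all")[, c("individual_id", "chimeric",
                                "matched_loci", "positive", "note")]
    }
    if (!is.null(panel) && nrow(cancer_genotype) > 0) {
      lineage_calls <- assign_lineages(cancer_genotype, panel)
    }
  }

  # mitochondrial sexing from mantle 16S ---------------------------
  m_ref <- filter(cohort$references, .data$locus == "16S",
                  .data$allele == "M_ancestor")$sequence
  f_ref <- filter(cohort$references, .data$locus == "16S",
                  .data$allele == "F_ancestor")$sequence
  sex_inferred <- map_chr(spec$id, function(id) {
    mantle <- filter(cohort$genotypes, .data$individual_id == id,
                     .data$locus == "16S", .data$tissue == "mantle")
    mito_sex(mantle, m_ref, f_ref)
  })

  report_spec <- left_join(
    mutate(spec, sex_inferred = sex_inferred),
    flow, by = "id"
  )
  report_spec <- left_join(
    report_spec,
    select(btn_calls, id = "individual_id", "chimeric", "positive"),
    by = "id"
  )
  report_spec <- mutate(
    report_spec,
    chimeric = dplyr::coalesce(.data$chimeric, FALSE),
    positive = dplyr::coalesce(.data$positive, FALSE)
  )
  structure(
    list(specimens = report_spec, flow = flow, genotypes = genotypes,
         chimerism = chimerism, cancer_genotype = cancer_genotype,
         btn_calls = btn_calls, lineage_calls = lineage_calls,
         cohort = cohort, config = config),
    class = "btn_report"
  )
}

empty_cancer_genotype <- function() {
  structure(
    tibble(locus = character(), allele = character(),
           sequence = character(), support = integer()),
    class = c("cancer_genotype", class(tibble()))
  )
}

#' @export
print.btn_report <- function(x, ...) {
  cat("<btn_report> ", nrow(x$specimens), " specimens; ",
      sum(x$specimens$dn_status == "dn_suggested"), " DN-suggested; ",
      sum(x$specimens$positive), " BTN-positive\n", sep = "")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `btn_report`.
#' @param ... Unused.
#' @method tidy btn_report
#' @export
tidy.btn_report <- function(x, ...) as_tibble(x$specimens)

#' @rdname run_pipeline
#' @method glance btn_report
#' @export
glance.btn_report <- function(x, ...) {
  tibble(
    n_specimens = nrow(x$specimens),
    n_dn_suggested = sum(x$specimens$dn_status == "dn_suggested"),
    n_chimeric = sum(x$specimens$chimeric),
    n_btn_positive = sum(x$specimens$positive),
    n_cancer_alleles = nrow(x$cancer_genotype)
  )
}

#' Write a pipeline report to plain-text files
#'
#' Emits `report.tsv` (per-specimen summary), `genotypes.tsv`,
#' `btn_calls.tsv`, `cancer_genotype.fasta` and, when present,
#' `lineage_calls.tsv`. Output is byte-identical across runs with the
#' same configuration.
#'
#' @param report A `btn_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_tsv(report$specimens, file.path(dir, "report.tsv"))
  if (!is.null(report$genotypes)) {
    write_table_tsv(report$genotypes, file.path(dir, "genotypes.tsv"))
  }
  write_table_tsv(report$btn_calls, file.path(dir, "btn_calls.tsv"))
  if (nrow(report$cancer_genotype) > 0) {
    write_fasta(
      tibble(
        name = sprintf("%s|%s|support=%d", report$cancer_genotype$locus,
                       report$cancer_genotype$allele,
                       report$cancer_genotype$support),
        sequence = report$cancer_genotype$sequence
      ),
      file.path(dir, "cancer_genotype.fasta")
    )
  }
  if (!is.null(report$lineage_calls)) {
    write_table_tsv(report$lineage_calls,
                    file.path(dir, "lineage_calls.tsv"))
  }
  invisible(dir)
}

#' Demonstration pipeline configuration
#'
#' A 12-specimen cohort with four infected mussels at the neoplastic
#' fractions of the four worked-example cases (26.4%, 44.4%, 80%, 91%)
#' plus healthy controls; cloning at 16 colonies with a 5% artifact rate.
#'
#' @param seed Seed for the run.
#' @return A [sim_config()].
#' @export
demo_pipeline_config <- function(seed = 2019) {
  sim_config(
    seed = seed, n_specimens = 12, prevalence = 4 / 12,
    neoplastic_fractions = c(0.264, 0.444, 0.80, 0.91),
    n_colonies = 16, artifact_rate = 0.05
  )
}
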