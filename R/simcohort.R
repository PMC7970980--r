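# Synthetic cohort simulator. Generates mussel cohorts with the genetic
# and cytometric structure the downstream analysis assumes: host nuclear
# and mitochondrial diversity, DUI sex structure (females homoplasmic for
# F-mtDNA; males additionally carry M-mtDNA in the mantle/gonad), a diploid
# cancer clone with two divergent nuclear alleles and recombinant control
# regions, cloning noise and fluorescence mixtures.

LOCI <- c("EF1a", "COI", "CR", "16S")
TISSUES <- c("hemolymph", "foot", "mantle")

#' Flow-cytometer acquisition parameters
#'
#' @param n_events Number of events per specimen (convention: at least
#'   10,000).
#' @param cv Coefficient of variation of each fluorescence component.
#' @param tetraploid_fraction_healthy Fraction of normal proliferating
#'   (tetraploid) cells in a healthy hemolymph sample.
#' @param diploid_mean Mean fluorescence of the diploid peak, in arbitrary
#'   instrument units.
#' @return A named list.
#' @export
flow_params <- function(n_events = 10000, cv = 0.05,
                        tetraploid_fraction_healthy = 0.02,
                        diploid_mean = 50) {
  stopifnot(n_events >= 1, cv > 0, diploid_mean > 0,
            tetraploid_fraction_healthy >= 0,
            tetraploid_fraction_healthy <= 1)
  list(
    n_events = as.integer(n_events), cv = cv,
    tetraploid_fraction_healthy = tetraploid_fraction_healthy,
    diploid_mean = diploid_mean
  )
}

#' Simulation configuration for a synthetic cohort
#'
#' Defaults encode the study conditions the pipeline was designed around:
#' 16 colonies per cloning experiment, 10,000 flow events, a cancer
#' heterozygous nuclear genotype whose two alleles differ by 21
#' substitutions, neoplastic hemocyte fractions spanning 0.12--0.98 and
#' relative ploidies 3.7--5.2 n.
#'
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   full configuration including the seed.
#' @param n_specimens Number of mussels.
#' @param prevalence Fraction infected; `floor(prevalence * n_specimens)`
#'   specimens carry the cancer.
#' @param locus_lengths Named lengths (bp) of the four loci.
#' @param host_divergence Expected pairwise substitutions between two host
#'   alleles at a locus.
#' @param cancer_nuclear_divergence Substitutions between the two cancer
#'   EF1a alleles.
#' @param cr_breakpoints 0-based half-open interval of the M-derived
#'   control-region segment.
#' @param n_mito_haplotypes Number of cancer mitochondrial haplotypes (each
#'   infected specimen is homoplasmic for one of them).
#' @param neoplastic_fraction_range Range `[p_min, p_max]` for the fraction
#'   of neoplastic cells in infected hemolymph.
#' @param neoplastic_fractions Optional explicit vector of neoplastic
#'   fractions, recycled over infected specimens in order; overrides the
#'   range draw.
#' @param relative_ploidy_range Range of aneuploid relative ploidy (n
#'   units) for infected specimens.
#' @param foot_infiltration Fraction of cancer cells in the foot (0: the
#'   foot retains the pure host genotype).
#' @param n_colonies Colonies per cloning experiment.
#' @param artifact_rate Per-colony probability of a PCR/cloning artifact.
#' @param flow_params See [flow_params()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_specimens = 50,
                       prevalence = 0.08,
                       locus_lengths = c(EF1a = 450, COI = 630,
                                         CR = 622, `16S` = 500),
                       host_divergence = 6,
                       cancer_nuclear_divergence = 21,
                       cr_breakpoints = c(200, 400),
                       n_mito_haplotypes = 2,
                       neoplastic_fraction_range = c(0.12, 0.98),
                       neoplastic_fractions = NULL,
                       relative_ploidy_range = c(3.7, 5.2),
                       foot_infiltration = 0,
                       n_colonies = 16,
                       artifact_rate = 0.05,
                       flow_params = btnscreen::flow_params()) {
  stopifnot(
    prevalence >= 0, prevalence <= 1,
    foot_infiltration >= 0, foot_infiltration <= 1,
    artifact_rate >= 0, artifact_rate <= 1,
    all(neoplastic_fraction_range >= 0),
    all(neoplastic_fraction_range <= 1),
    n_specimens >= 1, n_colonies >= 1, n_mito_haplotypes >= 1,
    all(LOCI %in% names(locus_lengths))
  )
  if (cr_breakpoints[1] >= cr_breakpoints[2] ||
      cr_breakpoints[1] < 0 ||
      cr_breakpoints[2] > locus_lengths[["CR"]]) {
    abort("`cr_breakpoints` must satisfy 0 <= b1 < b2 <= CR length.")
  }
  if (cancer_nuclear_divergence > locus_lengths[["EF1a"]]) {
    abort("`cancer_nuclear_divergence` exceeds the EF1a locus length.")
  }
  structure(
    list(
      seed = as.integer(seed), n_specimens = as.integer(n_specimens),
      prevalence = prevalence, locus_lengths = locus_lengths,
      host_divergence = host_divergence,
      cancer_nuclear_divergence = cancer_nuclear_divergence,
      cr_breakpoints = cr_breakpoints,
      n_mito_haplotypes = as.integer(n_mito_haplotypes),
      neoplastic_fraction_range = neoplastic_fraction_range,
      neoplastic_fractions = neoplastic_fractions,
      relative_ploidy_range = relative_ploidy_range,
      foot_infiltration = foot_infiltration,
      n_colonies = as.integer(n_colonies),
      artifact_rate = artifact_rate,
      flow_params = flow_params
    ),
    class = "sim_config"
  )
}

# One host allele: the locus ancestor plus a Poisson number of private
# substitutions, so two random host alleles differ by `host_divergence`
# substitutions in expectation.
draw_host_allele <- function(ancestor, host_divergence) {
  mutate_sequence(ancestor, rpois(1, host_divergence / 2))
}

build_cancer_clone <- function(config, ancestors, m_cr_donor) {
  ef_g <- mutate_sequence(ancestors[["EF1a"]], 5)
  ef_h <- mutate_sequence(ef_g, config$cancer_nuclear_divergence)
  coi <- mutate_sequence(ancestors[["COI"]], 8)
  cr_f <- mutate_sequence(ancestors[["CR"]], 8)
  s16 <- mutate_sequence(ancestors[["16S"]], 4)
  haps <- vector("list", config$n_mito_haplotypes)
  for (k in seq_len(config$n_mito_haplotypes)) {
    coi_k <- if (k == 1) coi else mutate_sequence(coi, 6)
    cr_f_k <- if (k == 1) cr_f else mutate_sequence(cr_f, 15)
    haps[[k]] <- list(
      coi = coi_k,
      cr = make_recombinant_cr(cr_f_k, m_cr_donor, config$cr_breakpoints)
    )
  }
  list(
    id = "clone1",
    ef1a_alleles = c(G = ef_g, H = ef_h),
    mito_haplotypes = haps,
    s16 = s16,
    heteroplasmic = FALSE
  )
}

host_genotype <- function(id, sex, ancestors, m_16s, config) {
  hd <- config$host_divergence
  ef <- c(draw_host_allele(ancestors[["EF1a"]], hd),
          draw_host_allele(ancestors[["EF1a"]], hd))
  coi <- draw_host_allele(ancestors[["COI"]], hd)
  cr <- draw_host_allele(ancestors[["CR"]], hd)
  s16 <- draw_host_allele(ancestors[["16S"]], hd)
  rows <- list()
  for (tissue in TISSUES) {
    rows[[length(rows) + 1]] <- tibble(
      individual_id = id, locus = "EF1a", tissue = tissue,
      allele = c("hA", "hB"), sequence = ef, frequency = c(0.5, 0.5),
      origin = "host"
    )
    rows[[length(rows) + 1]] <- tibble(
      individual_id = id, locus = c("COI", "CR"), tissue = tissue,
      allele = "hF", sequence = c(coi, cr), frequency = 1, origin = "host"
    )
    if (tissue == "mantle" && sex == "male") {
      # DUI: the paternal M genome is confined to the male gonad (mantle).
      rows[[length(rows) + 1]] <- tibble(
        individual_id = id, locus = "16S", tissue = tissue,
        allele = c("hF", "hM"),
        sequence = c(s16, mutate_sequence(m_16s, rpois(1, hd / 2))),
        frequency = c(0.5, 0.5), origin = c("host", "host_m")
      )
    } else {
      rows[[length(rows) + 1]] <- tibble(
        individual_id = id, locus = "16S", tissue = tissue,
        allele = "hF", sequence = s16, frequency = 1, origin = "host"
      )
    }
  }
  bind_rows(rows)
}

#' Mix a cancer genotype into a host specimen's tissues
#'
#' The hemolymph becomes a mixture with total cancer allele weight `p`
#' (cell fraction equals allele fraction: one cancer genome equivalent per
#' neoplastic cell); the foot mixes at `foot_infiltration`; the mantle is
#' unchanged. Within the cancer contribution, the two nuclear alleles each
#' get `p/2` and the mitochondrial haplotype gets `p`.
#'
#' @param genotypes Long genotype tibble for one specimen (columns
#'   `individual_id, locus, tissue, allele, sequence, frequency, origin`).
#' @param clone Cancer clone as built by [generate_cohort()] (list with
#'   `ef1a_alleles`, `mito_haplotypes`, `s16`).
#' @param p Neoplastic cell fraction in the hemolymph, in `[0, 1]`.
#' @param mito_haplotype Which of the clone's mitochondrial haplotypes this
#'   specimen carries.
#' @param foot_infiltration Cancer cell fraction in the foot.
#' @return The genotype tibble with mixed frequencies.
#' @export
infect <- function(genotypes, clone, p, mito_haplotype = 1,
                   foot_infiltration = 0) {
  stopifnot(p >= 0, p <= 1)
  hap <- clone$mito_haplotypes[[mito_haplotype]]
  hap_tag <- paste0("C", mito_haplotype)
  cancer_rows <- function(id, tissue) {
    bind_rows(
      tibble(
        individual_id = id, locus = "EF1a", tissue = tissue,
        allele = c("G", "H"), sequence = unname(clone$ef1a_alleles),
        frequency = 0.5, origin = "cancer"
      ),
      tibble(
        individual_id = id, locus = c("COI", "CR", "16S"), tissue = tissue,
        allele = c(paste0("COI-", hap_tag), paste0("CR-", hap_tag),
                   "16S-C"),
        sequence = c(hap$coi, hap$cr, clone$s16),
        frequency = 1, origin = "cancer"
      )
    )
  }
  mix_tissue <- function(tbl, tissue, w) {
    host <- filter(tbl, .data$tissue == !!tissue)
    if (w == 0) return(host)
    id <- host$individual_id[[1]]
    host$frequency <- host$frequency * (1 - w)
    cancer <- cancer_rows(id, tissue)
    cancer$frequency <- cancer$frequency * w
    bind_rows(host, cancer)
  }
  bind_rows(
    mix_tissue(genotypes, "hemolymph", p),
    mix_tissue(genotypes, "foot", foot_infiltration),
    filter(genotypes, .data$tissue == "mantle")
  )
}

#' Generate a synthetic mussel cohort
#'
#' Builds `n_specimens` hosts with 1:1 sexes under DUI, infects
#' `floor(prevalence * n_specimens)` of them with a shared cancer clone at
#' neoplastic fractions drawn from `neoplastic_fraction_range` (or taken
#' from `neoplastic_fractions`), and records every latent variable in a
#' truth table. Deterministic given the configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @return An object of class `btn_cohort`: a list with tibbles
#'   `specimens` (truth table), `genotypes` (per
#'   individual/locus/tissue/allele frequencies), `clones` (cancer allele
#'   sequences), `references` (locus ancestors and the M-mtDNA donor), and
#'   the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    ancestors <- lapply(config$locus_lengths[LOCI], random_sequence)
    names(ancestors) <- LOCI
    # M-mtDNA is deeply divergent from F-mtDNA (order 10% here).
    m_16s <- mutate_sequence(ancestors[["16S"]],
                             round(0.1 * config$locus_lengths[["16S"]]))
    m_cr <- mutate_sequence(ancestors[["CR"]],
                            round(0.1 * config$locus_lengths[["CR"]]))
    clone <- build_cancer_clone(config, ancestors, m_cr)

    n <- config$n_specimens
    ids <- sprintf("S%03d", seq_len(n))
    sexes <- sample(rep(c("female", "male"), length.out = n))
    n_inf <- floor(round(config$prevalence * n, 9))
    infected_idx <- if (n_inf > 0) sort(sample.int(n, n_inf)) else integer()
    p_vals <- if (n_inf == 0) {
      numeric()
    } else if (!is.null(config$neoplastic_fractions)) {
      rep_len(config$neoplastic_fractions, n_inf)
    } else {
      runif(n_inf, config$neoplastic_fraction_range[1],
            config$neoplastic_fraction_range[2])
    }
    hap_idx <- if (n_inf > 0) {
      sample.int(config$n_mito_haplotypes, n_inf, replace = TRUE)
    } else integer()
    rp <- if (n_inf > 0) {
      runif(n_inf, config$relative_ploidy_range[1],
            config$relative_ploidy_range[2])
    } else numeric()

    genotypes <- vector("list", n)
    spec <- tibble(
      id = ids, site = "SIM", sex = sexes,
      infected = seq_len(n) %in% infected_idx,
      clone_id = NA_character_, mito_haplotype = NA_integer_,
      neoplastic_fraction = 0, relative_ploidy = 2
    )
    for (i in seq_len(n)) {
      g <- host_genotype(ids[i], sexes[i], ancestors, m_16s, config)
      if (i %in% infected_idx) {
        k <- match(i, infected_idx)
        g <- infect(g, clone, p_vals[k], hap_idx[k],
                    config$foot_infiltration)
        spec$clone_id[i] <- clone$id
        spec$mito_haplotype[i] <- hap_idx[k]
        spec$neoplastic_fraction[i] <- p_vals[k]
        spec$relative_ploidy[i] <- rp[k]
      }
      genotypes[[i]] <- g
    }

    clones <- bind_rows(
      tibble(clone_id = clone$id, locus = "EF1a",
             allele = c("G", "H"),
             sequence = unname(clone$ef1a_alleles)),
      list_rbind(imap(clone$mito_haplotypes, function(h, k) {
        tibble(clone_id = clone$id, locus = c("COI", "CR"),
               allele = paste0(c("COI-C", "CR-C"), k),
               sequence = c(h$coi, h$cr))
      })),
      tibble(clone_id = clone$id, locus = "16S", allele = "16S-C",
             sequence = clone$s16)
    )
    references <- bind_rows(
      tibble(locus = LOCI, allele = "F_ancestor",
             sequence = unlist(ancestors[LOCI], use.names = FALSE)),
      tibble(locus = c("16S", "CR"), allele = "M_ancestor",
             sequence = c(m_16s, m_cr))
    )
    structure(
      list(
        specimens = spec,
        genotypes = bind_rows(genotypes),
        clones = clones,
        clone = clone,
        references = references,
        config = config
      ),
      class = "btn_cohort"
    )
  })
}

#' @export
print.btn_cohort <- function(x, ...) {
  cat("<btn_cohort> ", nrow(x$specimens), " specimens, ",
      sum(x$specimens$infected), " infected (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Simulate a molecular-cloning experiment
#'
#' Draws `n_colonies` colony sequences multinomially from the tissue's
#' allele frequencies. Each colony independently becomes a PCR/cloning
#' artifact with probability `artifact_rate`: its sequence is replaced by a
#' 1--2-substitution mutant guaranteed unique in the experiment (and
#' distinct from any sequence in `avoid`), emulating polymerase errors.
#'
#' @param tissue_genotype Genotype tibble rows for one
#'   individual/locus/tissue with `sequence` and `frequency` columns
#'   (frequencies sum to 1).
#' @param n_colonies Number of colonies sequenced.
#' @param artifact_rate Per-colony artifact probability.
#' @param avoid Extra sequences artifacts must not collide with.
#' @return A clone-set tibble: `individual_id, locus, tissue, colony_id,
#'   sequence`.
#' @export
simulate_cloning <- function(tissue_genotype, n_colonies = 16,
                             artifact_rate = 0, avoid = character()) {
  if (nrow(tissue_genotype) == 0) abort("Empty tissue genotype.")
  freq <- tissue_genotype$frequency
  if (abs(sum(freq) - 1) > 1e-6) {
    abort("Allele frequencies must sum to 1.")
  }
  picks <- sample.int(nrow(tissue_genotype), n_colonies,
                      replace = TRUE, prob = freq)
  seqs <- tissue_genotype$sequence[picks]
  forbidden <- c(tissue_genotype$sequence, avoid)
  is_artifact <- runif(n_colonies) < artifact_rate
  for (i in which(is_artifact)) {
    repeat {
      cand <- mutate_sequence(seqs[i], sample(1:2, 1))
      if (!cand %in% forbidden) break
    }
    forbidden <- c(forbidden, cand)
    seqs[i] <- cand
  }
  tibble(
    individual_id = tissue_genotype$individual_id[[1]] %||% NA_character_,
    locus = tissue_genotype$locus[[1]] %||% NA_character_,
    tissue = tissue_genotype$tissue[[1]] %||% NA_character_,
    colony_id = sprintf("c%02d", seq_len(n_colonies)),
    sequence = seqs
  )
}

#' Simulate a 1-D DNA-fluorescence event list
#'
#' Events are a truncated-normal mixture: a diploid component at the
#' diploid mean, a tetraploid component at twice that mean (normal
#' proliferating cells), and an aneuploid component at
#' `relative_ploidy / 2` times the diploid mean with weight `p_aneu`. All
#' components share the configured coefficient of variation; negative
#' draws are truncated to zero.
#'
#' @param p_aneu Aneuploid (neoplastic) event fraction, in `[0, 1]`.
#' @param relative_ploidy Aneuploid DNA content in n units relative to the
#'   specimen's 2n peak; must lie in `(2, 8]`. Ignored when `p_aneu` is 0.
#' @param params See [flow_params()].
#' @param specimen_id Identifier recorded with the events.
#' @return A tibble `specimen_id, intensity` with one row per event.
#' @export
simulate_flow_events <- function(p_aneu, relative_ploidy = 4.5,
                                 params = flow_params(),
                                 specimen_id = "S1") {
  stopifnot(p_aneu >= 0, p_aneu <= 1)
  if (p_aneu > 0 && (relative_ploidy <= 2 || relative_ploidy > 8)) {
    abort("`relative_ploidy` must lie in (2, 8].")
  }
  mu <- params$diploid_mean
  w_tet <- (1 - p_aneu) * params$tetraploid_fraction_healthy
  w_dip <- (1 - p_aneu) - w_tet
  means <- c(mu, 2 * mu, relative_ploidy / 2 * mu)
  weights <- c(w_dip, w_tet, p_aneu)
  comp <- sample.int(3, params$n_events, replace = TRUE, prob = weights)
  x <- rnorm(params$n_events, means[comp], params$cv * means[comp])
  tibble(specimen_id = specimen_id, intensity = pmax(x, 0))
}

#' Simulate a mixed Sanger chromatogram
#'
#' Per-site base calls for a two-template mixture: where the templates
#' agree there is a single call; where they differ the major template's
#' base is the main peak and the minor template's base appears as an
#' overlapping minor peak with relative height `ratio`.
#'
#' @param major,minor Aligned sequences of equal length.
#' @param ratio Minor-template fraction; must be below 0.5.
#' @return A tibble `position` (1-based), `major_base`, `minor_base` (`NA`
#'   at clean sites) and `minor_height`.
#' @export
simulate_chromatogram <- function(major, minor, ratio) {
  if (nchar(major) != nchar(minor)) {
    abort("Sequences must be aligned to equal length.")
  }
  stopifnot(ratio >= 0, ratio < 0.5)
  cm <- seq_chars(major)
  cn <- seq_chars(minor)
  mixed <- cm != cn
  tibble(
    position = seq_along(cm),
    major_base = cm,
    minor_base = ifelse(mixed, cn, NA_character_),
    minor_height = ifelse(mixed, ratio, 0)
  )
}
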