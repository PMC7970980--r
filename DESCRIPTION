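Package: btnscreen
Title: Genetic and Cytometric Screening for Bivalve Transmissible Neoplasia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection of bivalve transmissible neoplasia (BTN) from paired
    tissue genotypes and hemolymph DNA-content flow cytometry. Provides a
    synthetic cohort simulator with doubly uniparental mitochondrial
    inheritance and recombinant control regions, ploidy classification from
    fluorescence event lists, colony-based allele calling with artifact
    filtering, paired-tissue chimerism detection and two-evidence BTN
    calling, distance-based cancer lineage assignment, minimum spanning
    haplotype networks, and a maximum chi-square recombination breakpoint
    scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
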