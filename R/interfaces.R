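# File formats: FASTA records as name/sequence tibbles (Biostrings
# underneath), pipe-delimited header conventions, and tab-separated
# tables (UTF-8, header row, "." for missing).

#' Read a FASTA file into a tibble
#'
#' @param path FASTA file.
#' @return A tibble `name, sequence`. An empty file yields an empty
#'   tibble with a warning; duplicate record names or non-IUPAC
#'   characters raise a format error naming the offending records.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (file.size(path) == 0) {
    warn(sprintf("Empty FASTA file: %s", path))
    return(tibble(name = character(), sequence = character()))
  }
  # readDNAStringSet drops non-IUPAC letters with a warning; a silently
  # shortened sequence is worse than a refusal, so both become errors
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) {
        abort(sprintf("Not a valid DNA FASTA file (%s): %s",
                      path, conditionMessage(e)))
      }
    ),
    warning = function(w) {
      if (grepl("invalid", conditionMessage(w))) {
        abort(sprintf("Not a valid DNA FASTA file (%s): %s",
                      path, conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    }
  )
  nms <- names(set)
  dup <- unique(nms[duplicated(nms)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate FASTA record ids: ",
                 paste(dup, collapse = ", ")))
  }
  tibble(name = nms, sequence = unname(as.character(set)))
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, path))`
#' round-trips.
#'
#' @param records Tibble `name, sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(
    setNames(records$sequence, records$name)
  )
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Split pipe-delimited FASTA headers into fields
#'
#' Headers follow `field1|field2|...` conventions, e.g.
#' `lineage|locus|allele_name` for reference panels or
#' `specimen|locus|tissue|allele|freq` for cohort exports.
#'
#' @param records Tibble with a `name` column.
#' @param fields Field names, in header order.
#' @return `records` with one extra column per field.
#' @export
split_fasta_headers <- function(records, fields) {
  parts <- stringr::str_split(records$name, stringr::fixed("|"))
  bad <- map_int(parts, length) != length(fields)
  if (any(bad)) {
    abort(paste0("Malformed headers (expected ", length(fields),
                 " |-delimited fields): ",
                 paste(head(records$name[bad], 5), collapse = ", ")))
  }
  for (k in seq_along(fields)) {
    records[[fields[k]]] <- map_chr(parts, k)
  }
  records
}

#' Read a reference panel FASTA
#'
#' Panel records use `>lineage|locus|allele_name` headers; lineages are
#' typically `BTN1`, `BTN2`, `host_F`, `host_M`.
#'
#' @param path Panel FASTA file.
#' @return A tibble `lineage, locus, allele_name, sequence`.
#' @export
read_reference_panel <- function(path) {
  rec <- read_fasta(path)
  rec <- split_fasta_headers(rec, c("lineage", "locus", "allele_name"))
  select(rec, "lineage", "locus", "allele_name", "sequence")
}

#' Write tabular results
#'
#' Tab-separated, UTF-8, header row, `.` for missing values -- a dialect
#' chosen for bit-exact diffing.
#'
#' @param x A data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = ".")
  invisible(path)
}

#' Export a simulated cohort to plain-text files
#'
#' Writes the truth table (`truth.tsv`), one multi-FASTA per locus with
#' `>specimen|locus|tissue|allele|freq` headers, and one single-column
#' intensity file per specimen under `flow/` when flow events are
#' supplied.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param flow_events Optional named list of event tibbles per specimen.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, flow_events = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_tsv(cohort$specimens, file.path(dir, "truth.tsv"))
  for (loc in unique(cohort$genotypes$locus)) {
    g <- filter(cohort$genotypes, .data$locus == loc)
    rec <- tibble(
      name = sprintf("%s|%s|%s|%s|%.4f", g$individual_id, g$locus,
                     g$tissue, g$allele, g$frequency),
      sequence = g$sequence
    )
    write_fasta(rec, file.path(dir, paste0(loc, ".fasta")))
  }
  if (!is.null(flow_events)) {
    fdir <- file.path(dir, "flow")
    dir.create(fdir, showWarnings = FALSE)
    for (id in names(flow_events)) {
      ev <- flow_events[[id]]
      readr::write_tsv(
        setNames(tibble(ev$intensity), id),
        file.path(fdir, paste0(id, ".tsv"))
      )
    }
  }
  invisible(dir)
}

#' Read a one-column flow event file
#'
#' The header row carries the specimen id.
#'
#' @param path Single-column numeric TSV.
#' @return An event tibble `specimen_id, intensity`.
#' @export
read_flow_events <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_double()
  ))
  tibble(specimen_id = names(x)[[1]], intensity = x[[1]])
}
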