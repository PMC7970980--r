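# DNA sequence primitives shared by the simulator and the analysis stages.
# Sequences are plain uppercase character strings over A/C/G/T (alignment
# gaps "-" and ambiguous "N" are tolerated by comparison functions and
# treated as missing data). Interval coordinates are 0-based, half-open.

DNA_BASES <- c("A", "C", "G", "T")

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

#' Draw a random DNA sequence
#'
#' Uniform i.i.d. bases. Uses the current RNG stream; seed outside for
#' reproducibility.
#'
#' @param length Sequence length in bp.
#' @return A character scalar of `length` bases.
#' @export
random_sequence <- function(length) {
  stopifnot(is.numeric(length), length >= 1)
  chars_seq(sample(DNA_BASES, length, replace = TRUE))
}

#' Mutate a sequence by an exact number of substitutions
#'
#' Picks `n_subs` distinct positions without replacement and substitutes
#' each with a different base, so the Hamming distance between input and
#' output is exactly `n_subs`.
#'
#' @param ancestor DNA sequence (A/C/G/T only).
#' @param n_subs Number of substitutions; must not exceed the length.
#' @return The mutated sequence.
#' @examples
#' set.seed(1)
#' a <- random_sequence(100)
#' b <- mutate_sequence(a, 6)
#' p_distance(a, b)$n_diff  # 6
#' @export
mutate_sequence <- function(ancestor, n_subs) {
  stopifnot(is.character(ancestor), length(ancestor) == 1)
  chars <- seq_chars(ancestor)
  if (!all(chars %in% DNA_BASES)) {
    abort("`ancestor` must contain only A/C/G/T.")
  }
  if (n_subs > length(chars)) {
    abort("`n_subs` exceeds the sequence length.")
  }
  if (n_subs == 0) {
    return(ancestor)
  }
  pos <- sample.int(length(chars), n_subs)
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(DNA_BASES, b), 1)
  }, character(1))
  chars_seq(chars)
}

#' Splice an M-derived segment into an F-mtDNA backbone
#'
#' Builds a recombinant control region: the result equals `f_backbone`
#' outside the half-open interval `[b1, b2)` (0-based) and `m_donor` inside
#' it. This is the mosaic structure of "masculinized" mitochondrial control
#' regions carried by the BTN2 cancer lineage.
#'
#' @param f_backbone,m_donor Aligned sequences of equal length.
#' @param breakpoints Integer vector `c(b1, b2)`, 0-based half-open,
#'   `0 <= b1 < b2 <= length` (an empty interval `b1 == b2` is allowed and
#'   returns the backbone).
#' @return The recombinant sequence.
#' @export
make_recombinant_cr <- function(f_backbone, m_donor, breakpoints) {
  if (nchar(f_backbone) != nchar(m_donor)) {
    abort("`f_backbone` and `m_donor` must be aligned to the same length.")
  }
  L <- nchar(f_backbone)
  b1 <- breakpoints[[1]]
  b2 <- breakpoints[[2]]
  if (b1 < 0 || b2 > L || b1 > b2) {
    abort("`breakpoints` must satisfy 0 <= b1 <= b2 <= length.")
  }
  if (b1 == b2) {
    return(f_backbone)
  }
  paste0(
    substr(f_backbone, 1, b1),
    substr(m_donor, b1 + 1, b2),
    substr(f_backbone, b2 + 1, L)
  )
}

#' Uncorrected pairwise distance between aligned sequences
#'
#' Counts mismatching columns between two equal-length aligned sequences.
#' Columns where either sequence carries a gap (`-`) or an ambiguous base
#' are excluded (pairwise deletion), and the proportion is taken over the
#' compared columns only.
#'
#' @param a,b Aligned sequences of equal length.
#' @param gap_policy Only `"pairwise_deletion"` is supported.
#' @return A list with `n_diff`, `n_compared` and `p_dist`
#'   (`n_diff / n_compared`).
#' @examples
#' p_distance("ACGT", "ACGA")  # 1 difference over 4 sites
#' @export
p_distance <- function(a, b, gap_policy = "pairwise_deletion") {
  gap_policy <- match.arg(gap_policy)
  if (nchar(a) != nchar(b)) {
    abort("Sequences must be aligned to equal length.")
  }
  ca <- seq_chars(toupper(a))
  cb <- seq_chars(toupper(b))
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  n_compared <- sum(ok)
  n_diff <- sum(ca[ok] != cb[ok])
  list(
    n_diff = n_diff,
    n_compared = n_compared,
    p_dist = if (n_compared > 0) n_diff / n_compared else NA_real_
  )
}

# Pairwise n_diff matrix under pairwise deletion; used by the network
# builder and nearest-reference classifiers.
hamming_matrix <- function(sequences) {
  n <- length(sequences)
  m <- matrix(0L, n, n)
  if (n < 2) return(m)
  chars <- lapply(toupper(sequences), seq_chars)
  valid <- lapply(chars, function(x) x %in% DNA_BASES)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- valid[[i]] & valid[[j]]
      d <- sum(chars[[i]][ok] != chars[[j]][ok])
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}
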