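# Recombination breakpoint scanning on an aligned (query, parent A,
# parent B) triplet. A sliding window assigns each alignment segment to
# the parent the query matches better; flips in the assignment are
# candidate breakpoints, refined by maximizing the 2x2 chi-square of
# (left/right x matches-A/matches-B) over the informative sites near the
# flip. Coordinates are 0-based, half-open.

chi2_2x2 <- function(a, b, c, d) {
  # counts: left-matches-A, left-matches-B, right-matches-A,
  # right-matches-B; plain Pearson statistic without continuity correction
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(0)
  n * (a * d - b * c)^2 / denom
}

#' Scan a sequence for recombination breakpoints between two parents
#'
#' For each window the query's mismatches to each parent are counted and
#' the window assigned to the closer parent. Where the assignment flips,
#' the breakpoint is refined by maximizing the chi-square statistic of
#' the 2x2 table (left/right of the cut x query-matches-A/B) over the
#' informative sites (sites where the parents differ and the query
#' matches one of them) around the flip; the reported position is the
#' midpoint of the interval between the two informative sites flanking
#' the optimal cut. If one parent wins everywhere, no breakpoints are
#' reported.
#'
#' @param query,parent_a,parent_b Aligned sequences of equal length.
#' @param window Window width in bp (at least 20).
#' @param step Window step in bp (at least 1).
#' @param query_name Name carried into the report.
#' @return An object of class `recombination_scan` with `breakpoints`
#'   (0-based segment starts), `segments` (tiling of the alignment with a
#'   parent per segment; adjacent segments always differ), and `trace`
#'   (per-window mismatch counts and assignment). `tidy()` returns the
#'   segments.
#' @export
scan_recombination <- function(query, parent_a, parent_b, window = 50,
                               step = 10, query_name = "query") {
  L <- nchar(query)
  if (nchar(parent_a) != L || nchar(parent_b) != L) {
    abort("Query and parents must be aligned to equal length.")
  }
  if (window < 20) abort("`window` must be at least 20.")
  if (window > L) abort("`window` exceeds the alignment length.")
  if (step < 1) abort("`step` must be at least 1.")
  q <- seq_chars(toupper(query))
  a <- seq_chars(toupper(parent_a))
  b <- seq_chars(toupper(parent_b))
  valid <- q %in% DNA_BASES & a %in% DNA_BASES & b %in% DNA_BASES
  mis_a <- valid & q != a
  mis_b <- valid & q != b

  starts <- unique(c(seq(0, L - window, by = step), L - window))
  trace <- tibble(
    window_start = starts,
    window_end = starts + window,
    mism_a = map_int(starts, ~ sum(mis_a[(.x + 1):(.x + window)])),
    mism_b = map_int(starts, ~ sum(mis_b[(.x + 1):(.x + window)]))
  )
  raw <- ifelse(trace$mism_a < trace$mism_b, "A",
                ifelse(trace$mism_b < trace$mism_a, "B", NA))
  # for reporting, tie windows inherit the previous assignment (then the
  # next, at the start of the trace)
  winner <- raw
  for (i in seq_along(winner)) {
    if (is.na(winner[i]) && i > 1) winner[i] <- winner[i - 1]
  }
  for (i in rev(seq_along(winner))) {
    if (is.na(winner[i]) && i < length(winner)) winner[i] <- winner[i + 1]
  }
  trace$parent <- winner

  # informative sites, 0-based positions
  info <- which(valid & a != b & (q == a | q == b)) - 1L
  info_state <- ifelse(q[info + 1] == a[info + 1], "A", "B")

  # a flip lies between consecutive decisively assigned windows with
  # different winners; the region in between (which may include tie
  # windows without informative sites) brackets the breakpoint
  decisive <- which(!is.na(raw))
  flip_at <- which(raw[decisive][-1] !=
                     raw[decisive][-length(decisive)])
  breakpoints <- integer()
  for (f in flip_at) {
    i_left <- decisive[f]
    i_right <- decisive[f + 1]
    lo <- trace$window_start[i_left]
    hi <- trace$window_end[i_right]
    in_region <- info >= lo & info < hi
    pos <- info[in_region]
    st <- info_state[in_region]
    if (length(pos) == 0) {
      # no informative site in the flip region: take its midpoint
      breakpoints <- c(breakpoints, floor((lo + hi) / 2))
      next
    }
    if (length(pos) == 1) {
      breakpoints <- c(breakpoints, pos[[1]])
      next
    }
    # cut after site k: left = sites 1..k, right = k+1..end
    best_chi <- -1
    best_k <- NA_integer_
    for (k in seq_len(length(pos) - 1)) {
      chi <- chi2_2x2(
        sum(st[1:k] == "A"), sum(st[1:k] == "B"),
        sum(st[(k + 1):length(st)] == "A"),
        sum(st[(k + 1):length(st)] == "B")
      )
      if (chi > best_chi) {
        best_chi <- chi
        best_k <- k
      }
    }
    bp <- floor((pos[best_k] + 1 + pos[best_k + 1]) / 2)
    breakpoints <- c(breakpoints, bp)
  }
  breakpoints <- sort(unique(breakpoints))

  bounds <- c(0L, breakpoints, L)
  segments <- list_rbind(map(seq_len(length(bounds) - 1), function(i) {
    s <- bounds[i]
    e <- bounds[i + 1]
    in_seg <- info >= s & info < e
    par <- if (any(in_seg)) {
      names(which.max(table(info_state[in_seg])))
    } else NA_character_
    tibble(start = s, end = e, parent = par)
  }))
  # collapse any adjacent segments assigned to the same parent
  if (nrow(segments) > 1) {
    keep <- c(TRUE, segments$parent[-1] != segments$parent[-nrow(segments)])
    keep[is.na(keep)] <- TRUE
    segments$idx <- cumsum(keep)
    segments <- summarise(
      group_by(segments, .data$idx),
      start = min(.data$start), end = max(.data$end),
      parent = .data$parent[[1]], .groups = "drop"
    )
    segments <- select(segments, "start", "end", "parent")
    breakpoints <- segments$start[-1]
  }
  structure(
    list(query = query_name, breakpoints = as.integer(breakpoints),
         segments = segments, trace = trace,
         informative_sites = tibble(position = info, parent = info_state)),
    class = "recombination_scan"
  )
}

#' @export
print.recombination_scan <- function(x, ...) {
  if (length(x$breakpoints) == 0) {
    cat("<recombination_scan> ", x$query, ": no breakpoints\n", sep = "")
  } else {
    cat("<recombination_scan> ", x$query, ": breakpoints at ",
        paste(x$breakpoints, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname scan_recombination
#' @param x A `recombination_scan`.
#' @param ... Unused.
#' @method tidy recombination_scan
#' @export
tidy.recombination_scan <- function(x, ...) as_tibble(x$segments)

#' @rdname scan_recombination
#' @method glance recombination_scan
#' @export
glance.recombination_scan <- function(x, ...) {
  tibble(query = x$query, n_breakpoints = length(x$breakpoints),
         n_informative_sites = nrow(x$informative_sites))
}
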