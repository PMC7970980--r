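# DNA-content flow cytometry: histogram construction, peak detection,
# relative-ploidy assignment and the healthy / DN-suggested call.
#
# The classifier works on pre-gated 1-D fluorescence event lists (scatter
# gating and doublet removal are upstream instrument steps). Peaks are
# local maxima of a smoothed histogram; each peak is gated at +/- 3 sigma,
# with sigma estimated from the peak's full width at half maximum; relative
# ploidy is expressed in n units against the specimen's own 2n peak.

#' Bin a fluorescence event list
#'
#' Equal-width bins spanning `[0, max intensity]`; bin membership is
#' half-open on the left so counts always sum to the number of events.
#'
#' @param events Tibble with an `intensity` column (as produced by
#'   [simulate_flow_events()]) or a numeric vector.
#' @param n_bins Number of bins (at least 16).
#' @return A tibble `bin, lower, upper, mid, count` with attributes
#'   `total` and `binwidth`.
#' @export
build_histogram <- function(events, n_bins = 256) {
  x <- if (is.data.frame(events)) events$intensity else events
  if (length(x) == 0) abort("Empty event list.")
  if (n_bins < 16) abort("`n_bins` must be at least 16.")
  top <- max(x)
  if (top <= 0) top <- 1
  width <- top / n_bins
  idx <- pmin(floor(x / width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  h <- tibble(
    bin = seq_len(n_bins),
    lower = (seq_len(n_bins) - 1) * width,
    upper = seq_len(n_bins) * width,
    mid = (seq_len(n_bins) - 0.5) * width,
    count = counts
  )
  attr(h, "total") <- length(x)
  attr(h, "binwidth") <- width
  h
}

smooth_counts <- function(counts, k) {
  if (k <= 1) return(as.numeric(counts))
  s <- as.numeric(stats::filter(counts, rep(1 / k, k), sides = 2))
  s[is.na(s)] <- counts[is.na(s)]
  s
}

# FWHM-based spread estimate around a histogram mode, in intensity
# units (full width at half maximum of the smoothed counts). The walk
# stops if the counts climb back above the mode height, so the width of
# one peak can never extend through a neighbouring, taller peak.
peak_sigma <- function(smoothed, mids, i, binwidth) {
  half <- smoothed[i] / 2
  top <- smoothed[i]
  l <- i
  while (l > 1 && smoothed[l - 1] > half && smoothed[l - 1] <= top) {
    l <- l - 1
  }
  r <- i
  nb <- length(smoothed)
  while (r < nb && smoothed[r + 1] > half && smoothed[r + 1] <= top) {
    r <- r + 1
  }
  fwhm <- max(r - l + 1, 1) * binwidth
  max(fwhm / 2.355, binwidth)
}

# Topographic prominence of a candidate mode: its height above the higher
# of the two saddles separating it from taller ground.
peak_prominence <- function(smoothed, i) {
  h <- smoothed[i]
  saddle <- function(idx) {
    if (length(idx) == 0) return(0)
    low <- Inf
    for (k in idx) {
      if (smoothed[k] < low) low <- smoothed[k]
      if (smoothed[k] > h) return(low)
    }
    0
  }
  left <- saddle(rev(seq_len(i - 1)))
  right <- saddle(seq(i + 1, length.out = length(smoothed) - i))
  h - max(left, right)
}

gate_stats <- function(hist, lo, hi) {
  inside <- hist$mid >= lo & hist$mid <= hi
  n_in <- sum(hist$count[inside])
  mean <- if (n_in > 0) {
    weighted.mean(hist$mid[inside], hist$count[inside])
  } else NA_real_
  list(fraction = n_in / attr(hist, "total"), mean = mean)
}

#' Detect fluorescence peaks in a binned histogram
#'
#' Local maxima of the smoothed counts become candidate peaks; each is
#' gated at three estimated standard deviations and quantified as the
#' fraction of all events inside its gate. Peaks whose gated fraction
#' falls below `min_fraction` are dropped; peaks whose means are closer
#' than `min_separation` (as a ratio) are merged.
#'
#' @param hist Output of [build_histogram()].
#' @param min_fraction Minimum event fraction for a reported peak.
#' @param min_separation Minimum ratio between adjacent peak means.
#' @param smooth_bins Moving-average smoothing window (bins).
#' @return A tibble `mean, fraction, sigma, gate_lower, gate_upper`,
#'   ordered by mean intensity.
#' @export
detect_peaks <- function(hist, min_fraction = 0.01, min_separation = 1.05,
                         smooth_bins = 5) {
  if (nrow(hist) == 0) abort("Empty histogram.")
  binwidth <- attr(hist, "binwidth")
  s <- smooth_counts(hist$count, smooth_bins)
  nb <- length(s)
  is_max <- vapply(seq_len(nb), function(i) {
    left <- if (i > 1) s[i - 1] else -Inf
    right <- if (i < nb) s[i + 1] else -Inf
    s[i] > 0 && s[i] >= left && s[i] >= right &&
      (s[i] > left || s[i] > right)
  }, logical(1))
  cand <- which(is_max)
  if (length(cand) == 0) cand <- which.max(s)
  # drop shot-noise maxima: a credible mode must stand at least
  # min_fraction of the tallest mode high, and most of that height must
  # be its own prominence (not a ripple on another peak's tail)
  floor_h <- min_fraction * max(s)
  cand <- cand[s[cand] >= floor_h &
                 vapply(cand, function(i) peak_prominence(s, i),
                        numeric(1)) >= 0.5 * s[cand]]
  if (length(cand) == 0) cand <- which.max(s)
  peaks <- list_rbind(map(cand, function(i) {
    sigma <- peak_sigma(s, hist$mid, i, binwidth)
    lo <- hist$mid[i] - 3 * sigma
    hi <- hist$mid[i] + 3 * sigma
    g <- gate_stats(hist, lo, hi)
    tibble(mean = g$mean, fraction = g$fraction, sigma = sigma,
           gate_lower = lo, gate_upper = hi, height = s[i])
  }))
  peaks <- filter(peaks, !is.na(.data$mean))
  # Two candidate maxima inside one physical peak share a gate: keep the
  # taller before the fraction filter, then merge by separation.
  peaks <- arrange(peaks, desc(.data$height))
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(peaks))) {
      if (j == i || !keep[j]) next
      ratio <- max(peaks$mean[i], peaks$mean[j]) /
        min(peaks$mean[i], peaks$mean[j])
      if (ratio < min_separation) keep[j] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  peaks <- filter(peaks, .data$fraction >= min_fraction)
  peaks <- arrange(peaks, .data$mean)
  select(peaks, "mean", "fraction", "sigma", "gate_lower", "gate_upper")
}

#' Assign relative ploidy labels to detected peaks
#'
#' The diploid anchor is the lowest-mean peak whose fraction reaches
#' `diploid_anchor_fraction` (the 2n peak can be a small minority in heavy
#' disease, so the anchor is the lowest credible peak, not the largest).
#' Every peak's relative ploidy is `2 * mean / mean(anchor)`. A peak is
#' labeled tetraploid -- normal proliferating cells -- only when it lies
#' within `tetraploid_tolerance` of 4.0 n AND is a minor admixture
#' (fraction below `tetraploid_max_fraction`): a large near-4n population
#' is disease evidence, not normal proliferation, which also keeps
#' genuinely aneuploid populations near the band edge (3.7 n) from being
#' written off as tetraploid. All other non-anchor peaks are aneuploid.
#'
#' @param peaks Output of [detect_peaks()].
#' @param diploid_anchor_fraction Minimum fraction for the 2n anchor.
#' @param tetraploid_tolerance Half-width (n units) of the tetraploid band
#'   around 4.0.
#' @param tetraploid_max_fraction Largest event fraction compatible with
#'   normal proliferating tetraploid cells.
#' @return `peaks` with `relative_ploidy` and `label` columns.
#' @export
assign_ploidy <- function(peaks, diploid_anchor_fraction = 0.01,
                          tetraploid_tolerance = 0.3,
                          tetraploid_max_fraction = 0.05) {
  if (nrow(peaks) == 0) abort("No peaks to label.")
  anchor_ok <- peaks$fraction >= diploid_anchor_fraction
  if (!any(anchor_ok)) {
    abort("No peak qualifies as the diploid anchor.")
  }
  anchor_mean <- min(peaks$mean[anchor_ok])
  peaks$relative_ploidy <- 2 * peaks$mean / anchor_mean
  peaks$label <- ifelse(
    peaks$mean == anchor_mean, "diploid",
    ifelse(abs(peaks$relative_ploidy - 4) < tetraploid_tolerance &
             peaks$fraction < tetraploid_max_fraction,
           "tetraploid", "aneuploid")
  )
  peaks
}

#' Call a specimen healthy or DN-suggested from labeled peaks
#'
#' Healthy: a single diploid peak, or diploid plus a tetraploid admixture
#' below 5% (normal proliferating cells). DN-suggested: any aneuploid peak
#' reaching `min_aneuploid_fraction`. A tetraploid fraction of 5% or more
#' without an aneuploid peak is flagged `ambiguous_proliferative` rather
#' than forced into either class.
#'
#' @param peaks Labeled peaks from [assign_ploidy()].
#' @param min_aneuploid_fraction Detection floor for the aneuploid
#'   population.
#' @return An object of class `dn_diagnosis` with fields `status`,
#'   `aneuploid_fraction` and `peaks`.
#' @export
classify_dn <- function(peaks, min_aneuploid_fraction = 0.05) {
  stopifnot("label" %in% names(peaks))
  aneu <- filter(peaks, .data$label == "aneuploid")
  tetra_fraction <- sum(peaks$fraction[peaks$label == "tetraploid"])
  aneuploid_fraction <- sum(aneu$fraction)
  status <- if (any(aneu$fraction >= min_aneuploid_fraction)) {
    "dn_suggested"
  } else if (tetra_fraction >= 0.05) {
    "ambiguous_proliferative"
  } else {
    "healthy"
  }
  structure(
    list(status = status, aneuploid_fraction = aneuploid_fraction,
         tetraploid_fraction = tetra_fraction, peaks = peaks),
    class = "dn_diagnosis"
  )
}

#' One-call ploidy diagnosis from raw events
#'
#' Chains [build_histogram()], [detect_peaks()], [assign_ploidy()] and
#' [classify_dn()]. Warns when fewer than 10,000 events are supplied (the
#' acquisition convention the classifier was calibrated for).
#'
#' @param events Event tibble or numeric intensity vector.
#' @param n_bins,min_fraction,min_separation Histogram and peak-detection
#'   settings; see [detect_peaks()].
#' @param diploid_anchor_fraction,tetraploid_tolerance See
#'   [assign_ploidy()].
#' @param min_aneuploid_fraction See [classify_dn()].
#' @return A `dn_diagnosis`; its `histogram` field keeps the binned data
#'   for plotting.
#' @examples
#' set.seed(7)
#' ev <- simulate_flow_events(0.44, relative_ploidy = 4.5)
#' diagnose_ploidy(ev)
#' @export
diagnose_ploidy <- function(events, n_bins = 256, min_fraction = 0.01,
                            min_separation = 1.05,
                            diploid_anchor_fraction = 0.01,
                            tetraploid_tolerance = 0.3,
                            min_aneuploid_fraction = 0.05) {
  x <- if (is.data.frame(events)) events$intensity else events
  if (length(x) < 10000) {
    warn(sprintf("Only %d events; at least 10,000 are recommended.",
                 length(x)))
  }
  h <- build_histogram(x, n_bins)
  peaks <- detect_peaks(h, min_fraction, min_separation)
  peaks <- assign_ploidy(peaks, diploid_anchor_fraction,
                         tetraploid_tolerance)
  d <- classify_dn(peaks, min_aneuploid_fraction)
  d$histogram <- h
  if (is.data.frame(events) && "specimen_id" %in% names(events)) {
    d$specimen_id <- events$specimen_id[[1]]
  }
  d
}

#' @export
print.dn_diagnosis <- function(x, ...) {
  cat("<dn_diagnosis> status: ", x$status,
      sprintf(" (aneuploid fraction %.3f)\n", x$aneuploid_fraction),
      sep = "")
  print(x$peaks)
  invisible(x)
}

#' @rdname diagnose_ploidy
#' @param x A `dn_diagnosis`.
#' @param ... Unused.
#' @method tidy dn_diagnosis
#' @export
tidy.dn_diagnosis <- function(x, ...) {
  as_tibble(x$peaks)
}

#' @rdname diagnose_ploidy
#' @method glance dn_diagnosis
#' @export
glance.dn_diagnosis <- function(x, ...) {
  tibble(
    status = x$status,
    aneuploid_fraction = x$aneuploid_fraction,
    tetraploid_fraction = x$tetraploid_fraction,
    n_peaks = nrow(x$peaks)
  )
}
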