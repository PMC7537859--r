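# Fragment-level periodicity: random fragment sampling, windowed fits around
# the genomic period, period classification, and catenation rescue (pooling
# the spacing histograms of several weak-signal fragments so a shared
# underlying period becomes detectable).

#' Sample random fragments from a genome
#'
#' Fragment starts are uniform on the valid range; fragments may overlap.
#'
#' @param x A [genome_record()], sequence string, or genome length (bp).
#' @param n Number of fragments.
#' @param length Fragment length (bp).
#' @param seed Optional seed (caller's RNG state is preserved).
#' @return Data frame with `start` (1-based) and `length`.
#' @export
sample_fragments <- function(x, n, length = 40000L, seed = NULL) {
  L <- if (is.numeric(x)) as.integer(x) else nchar(as_sequence(x))
  length <- as.integer(length)
  if (length > L) stop("fragment length exceeds genome length", call. = FALSE)
  starts <- with_seed(seed, sample.int(L - length + 1L, n, replace = TRUE))
  data.frame(start = starts, length = length)
}

#' Classify a fragment period relative to the genomic period
#'
#' @param period Fitted period(s) (bp).
#' @param center Genomic period (bp); the search window is
#'   `center +/- window`.
#' @param tol Periods within `tol` bp of `center` are "genomic".
#' @param window Half-width of the period search window (bp); the outermost
#'   1-bp bands are the "low-extreme" / "high-extreme" classes.
#' @return Character vector: "genomic", "low-extreme", "high-extreme" or
#'   "other".
#' @export
classify_period <- function(period, center, tol = 0.6, window = 5) {
  lo <- center - window
  hi <- center + window
  out <- rep("other", length(period))
  out[period <= lo + 1] <- "low-extreme"
  out[period >= hi - 1] <- "high-extreme"
  out[abs(period - center) <= tol] <- "genomic"
  out
}

# constrained-window fit of one counts vector
fit_fragment_counts <- function(counts, max_spacing, center, window = 5,
                                max_lag = NULL, fit_lags = NULL) {
  h <- new_spacing_histogram(counts, max_spacing)
  period_fit(h, lambda_range = c(center - window, center + window),
             max_lag = max_lag, fit_lags = fit_lags)
}

#' Scan random fragments for periodicity
#'
#' Pools the spacings of the strongly periodic motif sets within each
#' fragment, fits the damped sine over periods within `window` bp of the
#' genomic period, and classifies each fragment's period.
#'
#' @param x A [genome_record()] or sequence string.
#' @param sets Motif sets to pool: the result of [strong_sets()] (or any
#'   subset of [motif_sets()] rows).
#' @param center Genomic period (bp), the window center.
#' @param n Number of fragments.
#' @param length Fragment length (bp).
#' @param window Half-width of the period search window (bp).
#' @param seed Optional seed (caller's RNG state is preserved).
#' @param max_spacing Largest spacing collated (bp).
#' @param tol "Genomic" classification tolerance (bp).
#' @return A `fragment_scan` object: `fragments` (data frame with `start`,
#'   `length`, `period`, `gdf`, `amplitude`, `category`), the per-fragment
#'   spacing `counts` matrix, and the scan settings.
#' @export
scan_fragments <- function(x, sets, center, n, length = 40000L, window = 5,
                           seed = NULL, max_spacing = 202L, tol = 0.6) {
  seq <- as_sequence(x)
  if (2L * max_spacing > length)
    stop("fragments shorter than twice the maximum spacing", call. = FALSE)
  codes <- dinuc_codes(encode_bases(seq))
  frags <- sample_fragments(nchar(seq), n, length, seed = seed)
  w <- pattern_weight_vector(set_member_patterns(sets))
  # edge correction: a fragment of length L offers L-1-d start-pair
  # opportunities at spacing d, a steep linear trend for short fragments
  # that would otherwise leak a positive baseline into the autocorrelation
  edge <- (length - 1) / (length - 1 - seq_len(max_spacing))
  counts <- matrix(0, nrow = n, ncol = max_spacing)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sl <- codes[frags$start[i]:(frags$start[i] + frags$length[i] - 2L)]
    cts <- counts_from_table(pair_count_table(sl, max_spacing), w) * edge
    counts[i, ] <- cts
    f <- fit_fragment_counts(cts, max_spacing, center, window)
    rows[[i]] <- data.frame(period = f$period, gdf = f$gdf,
                            amplitude = f$amplitude)
  }
  frags <- cbind(frags, do.call(rbind, rows))
  frags$category <- classify_period(frags$period, center, tol, window)
  structure(list(fragments = frags, counts = counts, center = center,
                 window = window, tol = tol, max_spacing = max_spacing),
            class = "fragment_scan")
}

#' @export
print.fragment_scan <- function(x, ...) {
  cat("Fragment periodicity scan: ", nrow(x$fragments), " fragments of ",
      format(x$fragments$length[1L], big.mark = ","), " bp, window ",
      x$center - x$window, "-", x$center + x$window, " bp\n", sep = "")
  print(round(100 * table(x$fragments$category) / nrow(x$fragments), 1))
  invisible(x)
}

#' Catenate fragments and refit
#'
#' Pools the spacing histograms of 1-5 pairwise non-overlapping fragments
#' (histogram summation, so no artificial junction spacings are created) and
#' refits over the same period window.  Used to rescue the genomic period
#' from fragments whose individual signal is too weak.
#'
#' @param scan A `fragment_scan`.
#' @param idx Row indices of the fragments to catenate.
#' @return A `period_fit` of the pooled histogram.
#' @export
catenate_fragments <- function(scan, idx) {
  stopifnot(inherits(scan, "fragment_scan"))
  fr <- scan$fragments[idx, , drop = FALSE]
  if (nrow(fr) > 1L) {
    o <- order(fr$start)
    s <- fr$start[o]; e <- fr$start[o] + fr$length[o] - 1L
    if (any(s[-1L] <= e[-length(e)]))
      stop("fragments overlap; catenation requires non-overlapping fragments",
           call. = FALSE)
  }
  counts <- colSums(scan$counts[idx, , drop = FALSE])
  fit_fragment_counts(counts, scan$max_spacing, scan$center, scan$window)
}
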