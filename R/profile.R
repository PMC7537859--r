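# Per-genome periodicity profiles over the 55 motif sets.

# member patterns of motif-set rows; accepts either a motif_sets() table or a
# gdf_profile (whose rows are matched back to the canonical sets by label)
set_member_patterns <- function(sets) {
  if (!all(c("member1", "member2") %in% names(sets))) {
    canon <- motif_sets()
    m <- match(sets$set, canon$set)
    if (anyNA(m)) stop("unknown motif set label(s)", call. = FALSE)
    sets <- canon[m, , drop = FALSE]
  }
  members <- c(sets$member1, sets$member2)
  members[!is.na(members)]
}

set_weight_list <- function(sets) {
  lapply(seq_len(nrow(sets)), function(i) {
    members <- c(sets$member1[i],
                 if (!is.na(sets$member2[i])) sets$member2[i])
    pattern_weight_vector(members)
  })
}

#' Periodicity profile of a genome over the motif sets
#'
#' For each palindromic or complementary-paired motif set, pools the member
#' patterns' spacings, smooths, autocorrelates, and fits the damped sine with
#' the period held fixed at the genomic period; the GdF, amplitude, strength
#' and significance flag of each constrained fit form the genome's profile.
#'
#' @param x A [genome_record()] or sequence string.
#' @param genomic The genomic period: a `period_fit`, a number (bp), or
#'   `NULL` to fit it from the pooled all-dinucleotide histogram first.
#' @param sets Motif-set table from [motif_sets()].
#' @param max_spacing Largest spacing collated (bp).
#' @param max_lag,fit_lags Passed to [autocorrelate()].
#' @return A data frame of class `gdf_profile` with one row per set: `set`,
#'   `palindromic`, `gdf`, `amplitude`, `half_life`, `strength`,
#'   `significant`; attributes `genomic_lambda`, `genomic_fit` and `genome`.
#' @export
gdf_profile <- function(x, genomic = NULL, sets = motif_sets(),
                        max_spacing = 202L, max_lag = NULL, fit_lags = NULL) {
  codes <- dinuc_codes(encode_bases(as_sequence(x)))
  tab <- pair_count_table(codes, max_spacing)
  genomic_fit <- NULL
  if (is.null(genomic)) {
    h <- new_spacing_histogram(
      counts_from_table(tab, pattern_weight_vector(dinucleotide_patterns())),
      max_spacing)
    genomic_fit <- period_fit(h, max_lag = max_lag, fit_lags = fit_lags)
    genomic <- genomic_fit$period
  } else if (inherits(genomic, "period_fit")) {
    genomic_fit <- genomic
    genomic <- genomic$period
  }
  wl <- set_weight_list(sets)
  rows <- lapply(seq_along(wl), function(i) {
    h <- new_spacing_histogram(counts_from_table(tab, wl[[i]]), max_spacing)
    f <- period_fit(h, lambda = genomic, max_lag = max_lag,
                    fit_lags = fit_lags)
    data.frame(set = sets$set[i], palindromic = sets$palindromic[i],
               gdf = f$gdf, amplitude = f$amplitude,
               half_life = f$half_life, strength = f$strength,
               significant = f$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "genomic_lambda") <- genomic
  attr(out, "genomic_fit") <- genomic_fit
  attr(out, "genome") <- if (inherits(x, "genome_record")) x$id else NA
  class(out) <- c("gdf_profile", "data.frame")
  out
}

#' Select strongly periodic motif sets
#'
#' Sets with GdF strictly below `gdf_max` and amplitude strictly above
#' `amplitude_min`; fragment-level scans pool only these sets to reduce
#' noise.
#'
#' @param profile A `gdf_profile`.
#' @param gdf_max,amplitude_min Strict thresholds (defaults 1.5 and 0.2).
#' @return The qualifying rows of `profile`.
#' @export
strong_sets <- function(profile, gdf_max = 1.5, amplitude_min = 0.2) {
  stopifnot(inherits(profile, "gdf_profile"))
  if (nrow(profile) == 0L) stop("empty profile", call. = FALSE)
  profile[profile$gdf < gdf_max & profile$amplitude > amplitude_min, ,
          drop = FALSE]
}

#' Correlation between two periodicity profiles
#'
#' Pearson correlation of the GdF values of two genomes over the same motif
#' sets; similar suites of periodic motifs give high correlations.
#'
#' @param a,b `gdf_profile`s (or data frames with `set` and `gdf` columns).
#' @return Pearson R.
#' @export
correlate_profiles <- function(a, b) {
  if (!identical(a$set, b$set)) {
    m <- match(a$set, b$set)
    if (anyNA(m)) stop("profiles cover different motif sets", call. = FALSE)
    b <- b[m, , drop = FALSE]
  }
  if (stats::sd(a$gdf) == 0 || stats::sd(b$gdf) == 0)
    stop("zero variance in a profile", call. = FALSE)
  stats::cor(a$gdf, b$gdf)
}

#' Deming (orthogonal) regression
#'
#' Errors-in-both-variables regression with error-variance ratio 1, the
#' symmetric choice when both axes carry the same noisy statistic.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return List with `slope` and `intercept`.
#' @export
deming_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 && syy == 0)
    stop("degenerate input: no variance on either axis", call. = FALSE)
  slope <- if (sxy == 0) {
    if (syy >= sxx) Inf else 0
  } else {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}
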