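# Cross-genome comparison: period differences, taxon-resampled periodicity
# frequencies, GC matching, metadata regressions.

#' Absolute period difference between two genomes
#'
#' Both fits must be significant (GdF < 3.0); non-significant genomes are
#' excluded from pairwise period comparisons.
#'
#' @param a,b `period_fit` objects.
#' @return `|period_a - period_b|` in bp, or `NA` (with a message) when
#'   either fit is not significant.
#' @export
period_difference <- function(a, b) {
  stopifnot(inherits(a, "period_fit"), inherits(b, "period_fit"))
  if (!a$significant || !b$significant) {
    message("period_difference: non-significant fit excluded (GdF >= 3.0)")
    return(NA_real_)
  }
  abs(a$period - b$period)
}

#' Summarize pairwise differences by relatedness class
#'
#' Per class, the median of the values together with the medians of the
#' values above and below that overall median (the error-bar convention used
#' for relatedness comparisons).
#'
#' @param values Pairwise statistics (e.g. `|delta period|` or profile R).
#' @param classes Relatedness class per pair (e.g. "genus", "family",
#'   "division").
#' @return Data frame with `class`, `n`, `median`, `lower_median`,
#'   `upper_median`.
#' @export
relatedness_summary <- function(values, classes) {
  stopifnot(length(values) == length(classes))
  keep <- !is.na(values)
  values <- values[keep]; classes <- classes[keep]
  out <- lapply(split(values, classes), function(v) {
    m <- stats::median(v)
    lower <- if (any(v < m)) stats::median(v[v < m]) else m
    upper <- if (any(v > m)) stats::median(v[v > m]) else m
    data.frame(n = length(v), median = m, lower_median = lower,
               upper_median = upper)
  })
  data.frame(class = names(out), do.call(rbind, out), row.names = NULL)
}

#' Taxon-resampled periodicity frequencies
#'
#' To avoid oversampling well-studied taxa, one genome is drawn at random
#' from each taxon (genus or family) per iteration, and the fraction of drawn
#' genomes in which each motif set is significantly periodic is recorded;
#' the mean and standard deviation over iterations are returned.
#'
#' @param significant Logical matrix, genomes x motif sets (row names are
#'   genome ids, column names set labels).
#' @param taxa Data frame with a `genome_id` column and taxonomy rank
#'   columns.
#' @param rank Column of `taxa` defining the taxa to resample (e.g.
#'   `"genus"` or `"family"`).
#' @param n_iter Number of resampling iterations (1500 by default).
#' @param seed Optional seed (caller's RNG state is preserved).
#' @return Data frame with `set`, `mean_pct`, `sd_pct`.
#' @export
periodic_fraction <- function(significant, taxa, rank = "genus",
                              n_iter = 1500L, seed = NULL) {
  significant <- as.matrix(significant)
  if (nrow(taxa) == 0L) stop("empty taxon table", call. = FALSE)
  if (!rank %in% names(taxa)) stop("no '", rank, "' column", call. = FALSE)
  idx <- match(taxa$genome_id, rownames(significant))
  if (anyNA(idx))
    stop("taxa table lists genomes without a profile row", call. = FALSE)
  groups <- split(idx, taxa[[rank]])
  freq <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    pick <- vapply(groups, function(g)
      if (length(g) == 1L) g else g[sample.int(length(g), 1L)], integer(1L))
    colMeans(significant[pick, , drop = FALSE]) * 100
  }, numeric(ncol(significant))))
  data.frame(set = colnames(significant),
             mean_pct = rowMeans(freq),
             sd_pct = apply(freq, 1L, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Match GC-content differences across relatedness classes
#'
#' Histogram matching with GC-difference bins: within each bin the same
#' number of pairs (the minimum over classes) is kept from every class, so
#' that comparisons between relatedness classes are not confounded by
#' increasingly different GC contents.
#'
#' @param dgc Absolute GC-content difference per pair (fraction, 0..1).
#' @param classes Relatedness class per pair.
#' @param bin Bin width on the GC-difference axis (default 0.01, i.e. 1%).
#' @param seed Optional seed (caller's RNG state is preserved).
#' @return Logical vector: pairs retained after matching.
#' @export
match_gc_differences <- function(dgc, classes, bin = 0.01, seed = NULL) {
  stopifnot(length(dgc) == length(classes))
  b <- floor(dgc / bin)
  cls <- unique(classes)
  keep <- logical(length(dgc))
  with_seed(seed, {
    for (bb in unique(b)) {
      in_bin <- which(b == bb)
      counts <- table(factor(classes[in_bin], levels = cls))
      n_target <- min(counts)
      if (n_target == 0L) next
      for (cc in cls) {
        cand <- in_bin[classes[in_bin] == cc]
        keep[if (length(cand) == n_target) cand else
          sample(cand, n_target)] <- TRUE
      }
    }
  })
  keep
}

#' Variance in period explained by a metadata covariate
#'
#' R-squared of the linear regression of genomic periods on a covariate such
#' as optimal growth temperature.
#'
#' @param period Genomic periods (bp).
#' @param covariate Numeric covariate (e.g. growth temperature, degrees C).
#' @return R-squared in `[0, 1]`.
#' @export
period_covariate_r2 <- function(period, covariate) {
  summary(stats::lm(period ~ covariate))$r.squared
}
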