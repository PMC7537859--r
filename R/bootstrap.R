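# Bootstrap variance of the period and per-motif period tests.
#
# Spacings are partitioned round-robin into k subsets at collation time (see
# collate_spacings); a bootstrap iterate draws k subsets with replacement,
# sums them into a histogram, and re-runs smoothing, autocorrelation and the
# damped-sine fit.  The spread of the resampled periods estimates the
# variance of the genuine period.

#' Bootstrap the period of a spacing histogram
#'
#' @param h A `spacing_histogram` collated with a subset partition
#'   (`collate_spacings(..., subsets = k)`).
#' @param n_iter Number of bootstrap iterates (1000 by default; 10,000 for
#'   tight confidence intervals).
#' @param seed Optional seed (caller's RNG state is preserved).
#' @param lambda_range Period search range for each refit.
#' @param max_lag,fit_lags Passed to [autocorrelate()].
#' @return A `period_boot` object: `periods` (fitted period per iterate),
#'   `mean`, `sd`, `n_iter`, `n_subsets`.
#' @export
bootstrap_period <- function(h, n_iter = 1000L, seed = NULL,
                             lambda_range = c(6, 16), max_lag = NULL,
                             fit_lags = NULL) {
  stopifnot(inherits(h, "spacing_histogram"))
  if (is.null(h$subsets))
    stop("histogram has no subset partition; collate with subsets = k",
         call. = FALSE)
  if (h$n_spacings == 0) stop("empty histogram", call. = FALSE)
  k <- nrow(h$subsets)
  template <- autocorrelate(smooth_counts(h$counts, h$max_spacing),
                            max_lag = max_lag, fit_lags = fit_lags)
  lags <- template$fit_lags
  sp <- attr(smooth_counts(h$counts, h$max_spacing), "spacings")
  periods <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    draw <- tabulate(sample.int(k, k, replace = TRUE), nbins = k)
    counts <- as.numeric(draw %*% h$subsets)
    v <- smooth_counts(counts, h$max_spacing)
    vv <- as.numeric(v)
    n <- length(vv)
    r <- vapply(lags, function(x)
      stats::cor(vv[1:(n - x)], vv[(1 + x):n]), numeric(1L))
    if (anyNA(r)) return(NA_real_)
    fit_core(r, lags, lambda_range)$lambda
  }, numeric(1L)))
  if (anyNA(periods)) {
    warning(sum(is.na(periods)), " degenerate bootstrap iterate(s) dropped")
    periods <- periods[!is.na(periods)]
  }
  structure(list(periods = periods, mean = mean(periods),
                 sd = stats::sd(periods), n_iter = n_iter, n_subsets = k),
            class = "period_boot")
}

#' @export
print.period_boot <- function(x, digits = 4L, ...) {
  cat("Bootstrap distribution of the period (", length(x$periods),
      " iterates, ", x$n_subsets, " subsets)\n", sep = "")
  cat("  mean ", format(x$mean, nsmall = 3), " bp, sd ",
      signif(x$sd, digits), " bp\n", sep = "")
  invisible(x)
}

#' Test a motif period against the genomic period
#'
#' Welch two-sample t-test comparing the bootstrap period distributions of an
#' individual motif and of the pooled (genomic) data.
#'
#' @param a,b `period_boot` objects (or plain numeric period vectors).
#' @return An object of class `htest` from [stats::t.test()].
#' @export
period_test <- function(a, b) {
  pa <- if (inherits(a, "period_boot")) a$periods else as.numeric(a)
  pb <- if (inherits(b, "period_boot")) b$periods else as.numeric(b)
  if (stats::sd(pa) == 0 && stats::sd(pb) == 0) {
    if (isTRUE(all.equal(mean(pa), mean(pb))))
      stop("both period distributions are constant and equal; ",
           "difference untestable", call. = FALSE)
    stop("zero variance in both period distributions", call. = FALSE)
  }
  stats::t.test(pa, pb)
}

#' Normality of variance-normalized motif periods
#'
#' Normalizes each significantly periodic motif's period as
#' `(period - genomic) / sd` and tests the normalized values against the
#' standard normal with a fully specified Kolmogorov-Smirnov test.  A genome
#' with a single underlying period gives standard-normal z-scores; a mixture
#' of periods is rejected.
#'
#' @param periods Fitted periods of the motifs (bp).
#' @param sds Bootstrap standard deviations of those periods (all > 0).
#' @param genomic Genomic period (bp).
#' @return An `htest` from [stats::ks.test()], or (when all normalized values
#'   coincide) a list marked untestable.
#' @export
period_normality_test <- function(periods, sds, genomic) {
  stopifnot(length(periods) == length(sds))
  if (length(periods) < 5L)
    stop("need at least 5 significantly periodic motifs", call. = FALSE)
  if (any(sds <= 0)) stop("all period sds must be positive", call. = FALSE)
  z <- (periods - genomic) / sds
  if (stats::sd(z) == 0)
    return(structure(list(untestable = TRUE, z = z,
                          reason = "all normalized periods identical"),
                     class = "period_normality"))
  stats::ks.test(z, "pnorm")
}

#' @export
print.period_normality <- function(x, ...) {
  cat("Normality of variance-normalized periods: untestable (",
      x$reason, ")\n", sep = "")
  invisible(x)
}
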