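# The user-facing fitting function and its model methods.

#' Fit the genomic period of a sequence
#'
#' The central fitting function: locates all (degenerate) dinucleotides, pools
#' their start-to-start spacings up to `max_spacing` bp, smooths the counts
#' over three bases, autocorrelates the smoothed abundances, and fits a damped
#' sine to the autocorrelation by grid search.  The fitted period of the
#' pooled all-dinucleotide histogram is the genomic period.
#'
#' @param x A [genome_record()], a sequence string, a `spacing_histogram`, or
#'   an `autocorr_series`.
#' @param ... Passed on between methods.
#' @return An object of class `period_fit` with components `period` (bp),
#'   `amplitude`, `half_life` (bp), `chi2`, `gdf`, `strength`
#'   (ln(GdF/A)), `significant` (GdF < 3), `sigma`, and the underlying
#'   `autocorr` series.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' set.seed(1)
#' g <- planted_genome(60000, period = 11, density = 4, jitter = 0.5)
#' fit <- period_fit(g$sequence)
#' coef(fit)
#' @export
period_fit <- function(x, ...) UseMethod("period_fit")

#' @rdname period_fit
#' @param patterns Degenerate dinucleotides to pool (default: all 100).
#' @param max_spacing Largest spacing collated (bp).
#' @param lambda_range Period search range (bp).
#' @param lambda Optional fixed period (constrained fit).
#' @param max_lag,fit_lags Passed to [autocorrelate()].
#' @export
period_fit.character <- function(x, patterns = dinucleotide_patterns(),
                                 max_spacing = 202L, lambda_range = c(6, 16),
                                 lambda = NULL, max_lag = NULL,
                                 fit_lags = NULL, ...) {
  h <- pooled_spacings(x, patterns, max_spacing)
  period_fit(h, lambda_range = lambda_range, lambda = lambda,
             max_lag = max_lag, fit_lags = fit_lags, ...)
}

#' @rdname period_fit
#' @export
period_fit.genome_record <- function(x, ...) {
  f <- period_fit(x$sequence, ...)
  f$genome <- x$id
  f
}

#' @rdname period_fit
#' @export
period_fit.spacing_histogram <- function(x, lambda_range = c(6, 16),
                                         lambda = NULL, max_lag = NULL,
                                         fit_lags = NULL, ...) {
  s <- smooth_spacings(x)
  ac <- autocorrelate(s, max_lag = max_lag, fit_lags = fit_lags)
  f <- fit_damped_sine(ac, lambda_range = lambda_range, lambda = lambda)
  f$n_spacings <- x$n_spacings
  f$smoothed <- s
  f
}

#' @rdname period_fit
#' @export
period_fit.autocorr_series <- function(x, lambda_range = c(6, 16),
                                       lambda = NULL, ...) {
  fit_damped_sine(x, lambda_range = lambda_range, lambda = lambda)
}

#' @export
print.period_fit <- function(x, digits = 4L, ...) {
  cat("Damped-sine periodicity fit",
      if (x$lambda_fixed) "(period held fixed)", "\n")
  cat("  period: ", format(x$period, nsmall = 2), " bp",
      "   amplitude: ", signif(x$amplitude, digits),
      "   half-life: ", signif(x$half_life, digits), " bp\n", sep = "")
  cat("  GdF: ", signif(x$gdf, digits),
      if (x$significant) "  (significant, GdF < 3.0)" else
        "  (not significant, GdF >= 3.0)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.period_fit <- function(object, ...) {
  structure(list(fit = object, resid = stats::residuals(object)),
            class = "summary.period_fit")
}

#' @export
print.summary.period_fit <- function(x, digits = 4L, ...) {
  print(x$fit, digits = digits)
  f <- x$fit
  cat("  chi^2: ", signif(f$chi2, digits),
      "   sigma: ", signif(f$sigma, digits),
      "   strength ln(GdF/A): ",
      if (is.na(f$strength)) "NA" else signif(f$strength, digits),
      "\n", sep = "")
  if (!is.na(f$n_spacings))
    cat("  spacings: ", format(f$n_spacings, big.mark = ","), "\n", sep = "")
  cat("  period search ", f$lambda_range[1L], "-", f$lambda_range[2L],
      " bp; fitted lags ", min(f$autocorr$fit_lags), "-",
      max(f$autocorr$fit_lags), "\n", sep = "")
  cat("  residuals: ")
  print(signif(stats::quantile(x$resid), digits))
  invisible(x)
}

#' @export
coef.period_fit <- function(object, ...) {
  c(period = object$period, amplitude = object$amplitude,
    half_life = object$half_life)
}

#' @export
predict.period_fit <- function(object, lags = object$autocorr$fit_lags, ...) {
  damped_sine(lags, object$period, object$amplitude, object$half_life)
}

#' @export
fitted.period_fit <- function(object, ...) {
  stats::predict(object)
}

#' @export
residuals.period_fit <- function(object, ...) {
  object$autocorr$r[object$autocorr$fit_lags] - stats::fitted(object)
}

#' @export
plot.period_fit <- function(x, ...) {
  ac <- x$autocorr
  graphics::plot(ac$lags, ac$r, pch = 16, cex = 0.6,
                 xlab = "lag (bp)", ylab = "autocorrelation", ...)
  xx <- seq(min(ac$fit_lags), max(ac$fit_lags), by = 0.1)
  graphics::lines(xx, stats::predict(x, lags = xx), col = "red")
  graphics::abline(h = 0, lty = 3, col = "grey")
  graphics::mtext(sprintf("period %.2f bp, GdF %.3g", x$period, x$gdf),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}

#' Simulate genomes with the fitted period
#'
#' Generates planted-period synthetic genomes whose motif lattice pitch equals
#' the fitted period, via [planted_genome()].
#'
#' @param object A `period_fit`.
#' @param nsim Number of genomes.
#' @param seed Optional seed (caller's RNG state is preserved).
#' @param length,motif,density,jitter,gc Passed to [planted_genome()].
#' @param ... Unused.
#' @return List of `nsim` results of [planted_genome()].
#' @export
simulate.period_fit <- function(object, nsim = 1L, seed = NULL,
                                length = 1e5, motif = "AA", density = 3,
                                jitter = 1, gc = 0.5, ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(i)
      planted_genome(length, period = object$period, motif = motif,
                     density = density, jitter = jitter, gc = gc))
  })
}

#' Permutation null distribution of the goodness of fit
#'
#' Randomizes the smoothed spacing abundances with respect to their spacing
#' intervals, autocorrelating and refitting the damped sine each time, to
#' obtain the distribution of GdF values expected for non-periodic data.
#' Because each permutation yields a fresh pseudo-random series (with its own
#' sigma), the null distribution is essentially independent of the genome
#' analyzed, which is what makes a single GdF threshold transferable across
#' genomes.  P-values for the observed GdF are reported both from a Gaussian
#' fitted to the null sample and as an empirical quantile.
#'
#' @param object A `period_fit` built from a histogram or sequence (so that
#'   the smoothed series is available), or a `smoothed_series`.
#' @param n_iter Number of permutations (>= 2).
#' @param seed Optional seed (caller's RNG state is preserved).
#' @param lambda_range Period search range for the refits (taken from the fit
#'   when `object` is a `period_fit`).
#' @return A `gdf_null` object: `samples`, `mean`, `sd`, `n_iter`, and (when
#'   available) `observed_gdf` with its Gaussian and empirical p-values.
#' @export
randomization_null <- function(object, n_iter = 10000L, seed = NULL,
                               lambda_range = NULL) {
  if (n_iter < 2L) stop("n_iter must be >= 2", call. = FALSE)
  observed_gdf <- NA_real_
  if (inherits(object, "period_fit")) {
    if (is.null(object$smoothed))
      stop("fit carries no smoothed series; fit from a histogram or sequence",
           call. = FALSE)
    s <- object$smoothed
    ac <- object$autocorr
    observed_gdf <- object$gdf
    if (is.null(lambda_range) && !object$lambda_fixed)
      lambda_range <- object$lambda_range
    max_lag <- length(ac$r)
    x <- ac$fit_lags
  } else if (inherits(object, "smoothed_series")) {
    s <- object
    max_lag <- length(as.numeric(s)) %/% 2L
    x <- 10:max_lag
  } else {
    stop("object must be a period_fit or smoothed_series", call. = FALSE)
  }
  if (is.null(lambda_range)) lambda_range <- c(6, 16)
  v <- as.numeric(s)
  n <- length(v)
  samples <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    vp <- sample(v)
    r <- vapply(x, function(l)
      stats::cor(vp[1:(n - l)], vp[(1 + l):n]), numeric(1L))
    if (anyNA(r)) return(NA_real_)
    f <- fit_core(r, x, lambda_range)
    f$chi2 / stats::sd(r)
  }, numeric(1L)))
  samples <- samples[!is.na(samples)]
  out <- list(samples = samples, mean = mean(samples),
              sd = stats::sd(samples), n_iter = n_iter,
              observed_gdf = observed_gdf)
  if (!is.na(observed_gdf)) {
    out$p_gaussian <- stats::pnorm(observed_gdf, out$mean, out$sd)
    out$p_empirical <- (1 + sum(samples <= observed_gdf)) / (n_iter + 1)
  }
  structure(out, class = "gdf_null")
}

#' @export
print.gdf_null <- function(x, digits = 4L, ...) {
  cat("Permutation null of the goodness of fit (", x$n_iter,
      " randomizations)\n", sep = "")
  cat("  null GdF: mean ", signif(x$mean, digits), ", sd ",
      signif(x$sd, digits), "\n", sep = "")
  if (!is.na(x$observed_gdf))
    cat("  observed GdF ", signif(x$observed_gdf, digits),
        ": Gaussian P = ", format(x$p_gaussian, digits = 3),
        ", empirical P = ", format(x$p_empirical, digits = 3), "\n", sep = "")
  invisible(x)
}
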