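# Autocorrelation of smoothed spacing abundances and the damped-sine fit.
#
# Model:  Y(x) = exp(-ln(2) * x / HL) * A * sin(2*pi*x/lambda + pi/2)
# with lambda the period (bp), A the amplitude (autocorrelation units) and HL
# the half-life (bp) of the exponential decay of phase coherence; the phase is
# fixed at pi/2 so Y(0) = A.  The fit minimizes chi^2 = sum of squared
# residuals over the fitted lags; GdF = chi^2 / sigma, with sigma the standard
# deviation of the observed autocorrelation values over those lags, and
# GdF < 3.0 defines a significant (robust) fit.

#' Autocorrelate a smoothed spacing series
#'
#' Pearson correlation of the smoothed spacing-abundance series with itself at
#' integer lags.  Periodic spacings give positive peaks at multiples of the
#' period; the fit ignores the first 9 lags to minimize the influence of
#' nucleotide repeats.
#'
#' @param s A `smoothed_series` (or plain numeric vector).
#' @param max_lag Largest lag (bp); defaults to half the spacing range.
#' @param fit_lags Lags used for curve fitting (default 10..`max_lag`).
#' @return An `autocorr_series`: list with `r` (correlations at lags
#'   `1..max_lag`), `fit_lags`, and `sigma` (sd of `r` over `fit_lags`).
#' @export
autocorrelate <- function(s, max_lag = NULL, fit_lags = NULL) {
  v <- as.numeric(s)
  n <- length(v)
  if (is.null(max_lag)) {
    sp <- attr(s, "spacings")
    max_lag <- if (!is.null(sp)) max(sp) %/% 2L else n %/% 2L
  }
  max_lag <- as.integer(max_lag)
  if (n < max_lag + 3L)
    stop("series too short for max_lag = ", max_lag, call. = FALSE)
  if (stats::sd(v) == 0)
    stop("constant spacing series: autocorrelation undefined", call. = FALSE)
  r <- vapply(seq_len(max_lag), function(x)
    stats::cor(v[1:(n - x)], v[(1 + x):n]), numeric(1L))
  if (anyNA(r))
    stop("degenerate spacing series: zero-variance window", call. = FALSE)
  if (is.null(fit_lags)) fit_lags <- 10:max_lag
  fit_lags <- as.integer(fit_lags[fit_lags >= 1L & fit_lags <= max_lag])
  if (!length(fit_lags)) stop("empty fit_lags", call. = FALSE)
  structure(list(r = r, lags = seq_len(max_lag), fit_lags = fit_lags,
                 sigma = stats::sd(r[fit_lags]), n_points = n),
            class = "autocorr_series")
}

#' @export
print.autocorr_series <- function(x, ...) {
  cat("<autocorr_series> lags 1..", length(x$r), ", fit lags ",
      min(x$fit_lags), "..", max(x$fit_lags),
      ", sigma = ", signif(x$sigma, 4), "\n", sep = "")
  invisible(x)
}

#' Damped sine curve
#'
#' @param x Lag (bp).
#' @param period Period lambda (bp), > 0.
#' @param amplitude Amplitude A (autocorrelation units), >= 0.
#' @param half_life Half-life HL (bp) of the exponential decay, > 0.
#' @return Predicted autocorrelation value(s).
#' @examples
#' damped_sine(0, 11, 0.8, 30)    # 0.8: sin(pi/2) = 1, no decay yet
#' damped_sine(20, 20, 1, 20)     # 0.5: one full cycle, one half-life
#' @export
damped_sine <- function(x, period, amplitude, half_life) {
  if (any(period <= 0) || any(half_life <= 0))
    stop("period and half_life must be positive", call. = FALSE)
  exp(-log(2) * x / half_life) * amplitude * sin(2 * pi * x / period + pi / 2)
}

#' Goodness of fit of a predicted curve
#'
#' GdF = chi^2 / sigma, where chi^2 is the sum of squared residuals over the
#' fitted lags and sigma the standard deviation of the observed values; lower
#' is better, and GdF < 3.0 marks a robust fit.
#'
#' @param observed,predicted Observed and predicted values over the same lags.
#' @param sigma Standard deviation of the observed (genuine) values.
#' @return The goodness of fit (dimensionless).
#' @export
goodness_of_fit <- function(observed, predicted, sigma) {
  stopifnot(length(observed) == length(predicted))
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  sum((observed - predicted)^2) / sigma
}

#' Strength of periodicity
#'
#' ln(GdF / A): smaller values indicate better fits with greater amplitude.
#' Undefined (returned as `NA`) when the amplitude or the GdF is zero.
#'
#' @param gdf Goodness of fit.
#' @param amplitude Fitted amplitude.
#' @return ln(GdF/A), or `NA` when undefined.
#' @export
periodicity_strength <- function(gdf, amplitude) {
  ifelse(is.na(gdf) | is.na(amplitude) | amplitude <= 0 | gdf <= 0,
         NA_real_, log(gdf / amplitude))
}

#' Is a fit significantly periodic?
#'
#' @param gdf Goodness-of-fit value(s).
#' @param threshold Strict GdF cutoff (default 3.0).
#' @return Logical: `gdf < threshold`.
#' @export
is_periodic <- function(gdf, threshold = 3.0) {
  gdf < threshold
}

# ---- grid search ------------------------------------------------------------

# coarse basis matrices are the same for every fit with the same grids; cache
.grid_cache <- new.env(parent = emptyenv())

# chi^2 minimization over a (lambda, A, HL) grid; ties broken by smallest
# lambda, then smallest A, then smallest HL (grids must be sorted ascending)
grid_search <- function(obs, x, lam_grid, a_grid, hl_grid, cache_key = NULL) {
  nl <- length(lam_grid); nh <- length(hl_grid); na <- length(a_grid)
  G <- NULL
  if (!is.null(cache_key)) G <- .grid_cache[[cache_key]]
  if (is.null(G)) {
    # rows: combos with lambda varying slowest, HL fastest
    decay <- exp(outer(hl_grid, x, function(h, xx) -log(2) * xx / h))
    cosx <- cos(2 * pi * outer(1 / lam_grid, x))
    G <- cosx[rep(seq_len(nl), each = nh), , drop = FALSE] *
      decay[rep(seq_len(nh), times = nl), , drop = FALSE]
    if (!is.null(cache_key)) .grid_cache[[cache_key]] <- G
  }
  og <- as.numeric(G %*% obs)
  gg <- rowSums(G * G)
  oo <- sum(obs * obs)
  # chi2 for each A is quadratic: oo - 2*A*og + A^2*gg
  arr <- vapply(a_grid, function(A) oo - 2 * A * og + A * A * gg,
                numeric(nl * nh))
  dim(arr) <- c(nh, nl, na)
  arr <- aperm(arr, c(1L, 3L, 2L))       # scan order: HL, A, lambda
  idx <- which.min(arr)
  ih <- (idx - 1L) %% nh + 1L
  ia <- ((idx - 1L) %/% nh) %% na + 1L
  il <- (idx - 1L) %/% (nh * na) + 1L
  list(lambda = lam_grid[il], amplitude = a_grid[ia],
       half_life = hl_grid[ih], chi2 = max(arr[idx], 0))
}

# full coarse-then-refined schedule on raw observed values; returns parameter
# list (used by fit_damped_sine, the permutation null and the bootstrap).
# a_obs_max is the maximum of the whole observed autocorrelation series
# (including unfitted small lags, where the largest values sit), which caps
# the amplitude grid at 120% of it.
fit_core <- function(obs, x, lambda_range = c(6, 16), lambda_fixed = NULL,
                     a_obs_max = max(obs)) {
  if (diff(lambda_range) < 0) stop("inverted lambda_range", call. = FALSE)
  # coarse grids: lambda 0.25 bp, A 0.05 from 0 to 120% of the observed
  # maximum, HL 5 bp between 5 and 60 bp
  lam_c <- if (!is.null(lambda_fixed)) lambda_fixed else
    seq(lambda_range[1L], lambda_range[2L], by = 0.25)
  a_max <- 1.2 * a_obs_max
  a_c <- if (a_max <= 0) 0 else seq(0, a_max, by = 0.05)
  hl_c <- seq(5, 60, by = 5)
  key <- if (is.null(lambda_fixed))
    paste0("c:", lambda_range[1L], ":", lambda_range[2L], ":",
           x[1L], ":", x[length(x)], ":", length(x)) else NULL
  est <- grid_search(obs, x, lam_c, a_c, hl_c, cache_key = key)
  # refinement: lambda 0.01 bp within +/- 0.8 bp, A 0.02 within +/- 20%,
  # HL 2% steps within +/- 20%; each grid contains the coarse estimate
  lam_f <- if (!is.null(lambda_fixed)) lambda_fixed else
    sort(unique(c(est$lambda,
                  round(seq(max(lambda_range[1L], est$lambda - 0.8),
                            min(lambda_range[2L], est$lambda + 0.8),
                            by = 0.01), 2))))
  a_f <- if (est$amplitude <= 0) 0 else
    sort(unique(c(est$amplitude,
                  seq(max(0, 0.8 * est$amplitude), 1.2 * est$amplitude,
                      by = 0.02))))
  hl_f <- seq(0.8, 1.2, by = 0.02) * est$half_life
  ref <- grid_search(obs, x, lam_f, a_f, hl_f)
  ref$coarse <- est[c("lambda", "amplitude", "half_life", "chi2")]
  ref
}

#' Fit a damped sine to an autocorrelation series
#'
#' Coarse-then-refined grid search minimizing the sum of squared residuals
#' over the fitted lags.  The period is explored from `lambda_range[1]` to
#' `lambda_range[2]` in 0.25-bp steps, the amplitude from 0 to 120% of the
#' maximum observed autocorrelation in 0.05 steps, and the half-life from 5 to
#' 60 bp in 5-bp steps; estimates are then refined in 0.01-bp (period),
#' 0.02 (amplitude) and 2%-of-estimate (half-life) steps within a
#' neighbourhood of the coarse estimate.  Ties are broken towards the smallest
#' period, then amplitude, then half-life.
#'
#' @param ac An `autocorr_series` from [autocorrelate()].
#' @param lambda_range Period search range `c(min, max)` in bp.
#' @param lambda Optional fixed period: only amplitude and half-life are
#'   searched (used when profiling individual motifs at the genomic period).
#' @return A `period_fit` object; see [period_fit()].
#' @export
fit_damped_sine <- function(ac, lambda_range = c(6, 16), lambda = NULL) {
  stopifnot(inherits(ac, "autocorr_series"))
  obs <- ac$r[ac$fit_lags]
  f <- fit_core(obs, ac$fit_lags, lambda_range, lambda_fixed = lambda,
                a_obs_max = max(ac$r))
  gdf <- f$chi2 / ac$sigma
  structure(list(period = f$lambda, amplitude = f$amplitude,
                 half_life = f$half_life, chi2 = f$chi2, gdf = gdf,
                 strength = periodicity_strength(gdf, f$amplitude),
                 significant = is_periodic(gdf), sigma = ac$sigma,
                 lambda_range = if (is.null(lambda))
                   as.numeric(lambda_range) else c(lambda, lambda),
                 lambda_fixed = !is.null(lambda), autocorr = ac,
                 n_spacings = NA_real_, call = sys.call(-1L)),
            class = "period_fit")
}
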