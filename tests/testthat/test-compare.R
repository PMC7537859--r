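test_that("a genome profile covers the 55 sets with flags consistent with GdF", {
  prof <- planted_profile()
  expect_equal(nrow(prof), 55L)
  expect_identical(prof$set, motif_sets()$set)
  expect_identical(prof$significant, prof$gdf < 3.0)
  expect_true(all(prof$amplitude >= 0))
  expect_gt(sum(prof$significant), 5)   # the planted motif lights up several sets
  expect_equal(attr(prof, "genomic_lambda"), planted_strong()$fit$period)
  # palindromic-set spacings equal the single member pattern's histogram
  g <- planted_strong()$genome
  pal <- motif_sets()$member1[motif_sets()$palindromic][1]
  hs <- pooled_spacings(g$sequence, pal)
  expect_equal(hs$counts,
               collate_spacings(scan_pattern(g$sequence, pal))$counts)
})

test_that("profile correlation is symmetric with exact fixed points", {
  prof <- planted_profile()
  expect_equal(correlate_profiles(prof, prof), 1.0)
  neg <- prof
  neg$gdf <- 2 * mean(prof$gdf) - prof$gdf
  expect_equal(correlate_profiles(prof, neg), -1.0)
  shuffled <- prof[sample(nrow(prof)), ]
  expect_equal(correlate_profiles(prof, shuffled), 1.0)  # aligned by set label
  expect_equal(correlate_profiles(prof, neg), correlate_profiles(neg, prof))
})

test_that("profiles of the two halves of a uniformly planted genome agree", {
  # a suite of motifs planted at graded densities at one shared period;
  # per-genome inter-arm R is itself a noisy statistic (sd ~ 0.06 at this
  # scale), so the sharing of periodic suites is asserted on the average
  rs <- vapply(11:13, function(s) {
    g0 <- planted_genome(6e5, 10.5, motif = c("AA", "GC", "RY", "CW"),
                         density = c(2.5, 1.2, 0.8, 0.5), jitter = 1,
                         seed = s)
    fit <- period_fit(g0$sequence)
    g <- genome_record(g0$sequence, origin = 1L, terminus = 3e5L)
    arms <- split_replicores(g)
    pr <- gdf_profile(arms$right$sequence, genomic = fit$period)
    pl <- gdf_profile(arms$left$sequence, genomic = fit$period)
    correlate_profiles(pr, pl)
  }, numeric(1))
  expect_gt(mean(rs), 0.7)
  expect_true(all(rs > 0.6))
})

test_that("Deming regression has its closed-form fixed points and axis symmetry", {
  x <- c(1, 2, 3, 4, 5)
  d <- deming_fit(x, x)
  expect_equal(d$slope, 1); expect_equal(d$intercept, 0)
  set.seed(6)
  xs <- rnorm(30); ys <- 0.7 * xs + rnorm(30, sd = 0.3)
  d1 <- deming_fit(xs, ys)
  d2 <- deming_fit(ys, xs)
  expect_equal(d1$slope, 1 / d2$slope, tolerance = 1e-9)
  # direct closed form
  sxx <- var(xs); syy <- var(ys); sxy <- cov(xs, ys)
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  expect_equal(d1$slope, slope)
  expect_equal(d1$intercept, mean(ys) - slope * mean(xs))
  expect_error(deming_fit(rep(1, 5), rep(2, 5)), "degenerate")
})

test_that("period differences require significant fits and summarize by class medians", {
  mkfit <- function(period, gdf) {
    structure(list(period = period, gdf = gdf, significant = gdf < 3),
              class = "period_fit")
  }
  expect_equal(period_difference(mkfit(11.07, 0.5), mkfit(9.93, 0.8)), 1.14)
  expect_equal(period_difference(mkfit(10.5, 0.5), mkfit(10.5, 0.5)), 0)
  expect_message(out <- period_difference(mkfit(10.5, 0.5), mkfit(9.9, 4.0)),
                 "excluded")
  expect_true(is.na(out))
  # class medians match a sort-based oracle
  set.seed(10)
  vals <- runif(50, 0, 2)
  cls <- sample(c("genus", "family"), 50, replace = TRUE)
  sm <- relatedness_summary(vals, cls)
  for (cc in unique(cls)) {
    v <- sort(vals[cls == cc])
    m <- median(v)
    row <- sm[sm$class == cc, ]
    expect_equal(row$median, m)
    expect_equal(row$lower_median, median(v[v < m]))
    expect_equal(row$upper_median, median(v[v > m]))
  }
})

test_that("taxon-resampled periodicity frequencies are calibrated and reproducible", {
  set.seed(2)
  sig <- matrix(runif(8 * 55) < 0.4, nrow = 8,
                dimnames = list(paste0("g", 1:8), motif_sets()$set))
  taxa <- data.frame(genome_id = paste0("g", 1:8),
                     genus = c("a", "a", "b", "b", "b", "c", "d", "d"))
  f1 <- periodic_fraction(sig, taxa, rank = "genus", n_iter = 200, seed = 5)
  f2 <- periodic_fraction(sig, taxa, rank = "genus", n_iter = 200, seed = 5)
  expect_identical(f1, f2)
  expect_true(all(f1$mean_pct >= 0 & f1$mean_pct <= 100))
  # one genome per taxon: deterministic frequencies, zero variance
  taxa1 <- data.frame(genome_id = paste0("g", 1:4), genus = letters[1:4])
  f3 <- periodic_fraction(sig[1:4, ], taxa1, rank = "genus", n_iter = 50,
                          seed = 1)
  expect_true(all(f3$sd_pct == 0))
  expect_equal(f3$mean_pct, colMeans(sig[1:4, ]) * 100, ignore_attr = TRUE)
  expect_error(periodic_fraction(sig, taxa[0, ], rank = "genus"), "empty")
})

test_that("GC-difference matching equalizes class counts within bins", {
  set.seed(8)
  dgc <- c(runif(200, 0, 0.1), runif(100, 0.05, 0.2))
  cls <- rep(c("near", "far"), c(200, 100))
  keep <- match_gc_differences(dgc, cls, bin = 0.01, seed = 3)
  b <- floor(dgc / 0.01)
  for (bb in unique(b[keep])) {
    n_by_class <- table(cls[keep & b == bb])
    if (length(n_by_class) == 2) expect_equal(n_by_class[[1]], n_by_class[[2]])
  }
})

test_that("period-covariate regression explains little on independent data", {
  set.seed(12)
  r2 <- period_covariate_r2(rnorm(100, 10.8, 0.4), runif(100, 0, 90))
  expect_gte(r2, 0); expect_lte(r2, 1)
  expect_lt(r2, 0.1)
})
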