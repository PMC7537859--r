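# periodscope

Robust measurement of dinucleotide periodicity in genome sequences.

Many genomes show a faint ~10–11 bp periodicity in the spacings between
dinucleotide motifs — a signal of roughly one percent modulation in spacing
abundances, historically attributed to DNA bending but present in many
motifs with no role in bending.  Detecting it reliably, putting a variance
on the measured period, and deciding whether a fit is meaningful at all
requires more than a periodogram.  periodscope is aimed at comparative
genomicists who want to measure genomic periods, profile which motifs carry
the signal, compare those profiles between genomes, and validate every step
against synthetic genomes with known truth.

## The method

For each of the 100 dinucleotides over the IUPAC symbols
{G, A, T, C, R, Y, W, S, M, K}, occurrences are located and the
start-to-start spacings between all pairs up to 202 bp are collated.  Counts
are smoothed over a sliding 3-bp window (removing the codon-frame
periodicity), the smoothed series is autocorrelated at lags 1–100, and a
damped sine

```
Y(x) = exp(-ln(2) x / HL) * A * sin(2 pi x / lambda + pi/2)
```

is fitted over lags 10–100 by a deterministic coarse-then-refined grid
search minimizing the residual sum of squares chi².  Here `lambda` is the
period (bp), `A` the amplitude, and `HL` the half-life of the decay of phase
coherence caused by indels.  The goodness of fit is `GdF = chi²/sigma`
(`sigma` = sd of the observed autocorrelations over the fitted lags);
`GdF < 3.0` marks a robust fit, a threshold calibrated against a
permutation null in which the smoothed abundances are randomized with
respect to their spacings and refitted.  The variance of the period comes
from a 1000-subset bootstrap of the spacings.  Dinucleotides group into 55
palindromic / complementary-paired motif sets whose per-genome GdF profiles
support cross-genome comparison (Pearson correlation, Deming regression,
taxon-resampled periodicity frequencies), and random-fragment scans with
catenation rescue ask whether periodicity is chromosome-wide.

## A worked example

Plant a 10.5-bp periodic motif in a 300-kb synthetic genome and measure it
back:

```r
library(periodscope)

g   <- planted_genome(300000, period = 10.5, density = 3, jitter = 1, seed = 42)
fit <- period_fit(g$sequence)
fit
#> Damped-sine periodicity fit
#>   period: 10.52 bp   amplitude: 1.1   half-life: 72 bp
#>   GdF: 0.7617  (significant, GdF < 3.0)
```

The fitted period is within 0.02 bp of the planted truth and the fit is
robust (GdF well under 3.0).  Is it meaningful?  The permutation null says a
non-periodic genome of this composition would score GdF ≈ 7:

```r
randomization_null(fit, n_iter = 500, seed = 1)
#> Permutation null of the goodness of fit (500 randomizations)
#>   null GdF: mean 7.077, sd 0.7273
#>   observed GdF 0.7617: Gaussian P = 1.91e-18, empirical P = 0.002
```

How precise is the period?  Bootstrap the spacings of the planted motif:

```r
h    <- collate_spacings(scan_pattern(g$sequence, "AA"), subsets = 1000)
bootstrap_period(h, n_iter = 200, seed = 2)
#> Bootstrap distribution of the period (200 iterates, 1000 subsets)
#>   mean 10.4994 bp, sd 0.01317 bp
```

Which motif sets carry the signal?  Profile all 55 at the genomic period:

```r
prof <- gdf_profile(g$sequence, genomic = fit)
head(prof[order(prof$gdf), ], 3)
#>      set palindromic       gdf amplitude half_life  strength significant
#> 24 TW/WA       FALSE 0.9588687      1.18      72.0 -0.2075156        TRUE
#> 48 WM/KW       FALSE 1.1745835      0.80      66.0  0.3840572        TRUE
#> 42 YW/WR       FALSE 1.1994033      0.94      69.6  0.2436996        TRUE
sum(prof$significant)
#> [1] 17
```

Seventeen sets — those whose degenerate patterns overlap the planted AA
motif — are significantly periodic; unrelated sets are not.  `plot(fit)`
draws the autocorrelation with the fitted curve, and
`simulate(fit, nsim = 2, length = 1e5)` generates new genomes at the fitted
period.  A thin command-line interface is installed as `exec/periodscope`
(subcommands `scan`, `period`, `bootstrap`, `fragments`, `simulate`).

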