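---
title: "Measuring dinucleotide periodicity in genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dinucleotide periodicity in genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periodscope)
```

## The measurement problem

Many genomes carry dinucleotide motifs whose occurrences recur at a
preferred spacing close to the helical pitch of DNA (~10–11 bp).  The signal
is faint — on the order of a percent modulation of spacing abundances — and
sits on top of shot noise, codon-frame artifacts, and the slow loss of phase
coherence that insertions and deletions impose.  periodscope implements a
measurement pipeline designed for that regime:

1. **Scanning.**  All 100 dinucleotides over the IUPAC symbols G, A, T, C,
   R, Y, W, S, M, K are located (overlapping matches included; ambiguous
   genome bases never match).  Complements follow the table G↔C, A↔T, R↔Y,
   W↔W, S↔S, M↔K, which partitions the 100 patterns into 10 palindromes and
   45 complementary pairs — 55 motif sets whose members are pooled when
   profiled, since a motif and its complement are equally periodic on the
   two strands.
2. **Spacing collation.**  Start-to-start distances between *all* ordered
   pairs of occurrences up to 202 bp are counted.  All-pairs collation (as
   opposed to nearest-neighbour spacing) preserves the enrichment at every
   multiple of the period and makes the histogram independent of intervening
   occurrences.
3. **Smoothing.**  Counts are averaged over a forward sliding 3-bp window
   (the value reported at spacing *s* is the mean at *s*, *s*+1, *s*+2),
   cancelling the 3-bp periodicity imparted by the genetic code; spacings
   below 6 bp are discarded to suppress homopolymer runs.  The smoothed
   series runs over spacings 6–200.
4. **Autocorrelation.**  The smoothed series is correlated with itself at
   integer lags 1–100 (Pearson, windows trimmed to the overlap).  Periodic
   spacings give positive peaks at multiples of the period.
5. **Model fit.**  A damped sine

   *Y(x) = exp(−ln 2 · x / HL) · A · sin(2πx/λ + π/2)*

   is fitted to the autocorrelation over lags 10–100 by minimizing the sum
   of squared residuals (χ²).  λ is the period (bp), *A* the amplitude in
   correlation units, and *HL* the half-life (bp) of the decay of phase
   coherence.  The phase is fixed at π/2 so the undamped curve peaks at
   lag 0.

### The grid search

Optimization is a coarse-then-refined grid search, fully deterministic:
λ from 6 to 16 bp in 0.25-bp steps, *A* from 0 to 120% of the maximum
observed autocorrelation in 0.05 steps, *HL* from 5 to 60 bp in 5-bp steps;
then λ in 0.01-bp steps within ±0.8 bp of the coarse estimate, *A* in 0.02
steps within ±20%, and *HL* in 2%-of-estimate steps within ±20%.  Because χ²
is quadratic in *A*, the amplitude axis is evaluated in closed form at the
grid values.  Ties are broken towards the smallest λ, then *A*, then *HL*,
so results are reproducible to the digit.  Every refinement grid contains
the coarse estimate, so refinement can never increase χ².  Note that the
schedule quantizes the optimum: a curve whose true parameters fall between
refinement grid points is recovered at grid resolution (0.01 bp in λ, 0.02
in *A*, 2% in *HL*), not exactly.

### Goodness of fit and significance

The goodness of fit is GdF = χ²/σ, with σ the standard deviation of the
observed autocorrelation values over the fitted lags; χ² is the raw sum of
squared residuals (a division-form χ² would be ill-posed for signed,
near-zero correlations).  GdF < 3.0 (strict) flags a robust fit.

Significance is calibrated by a randomization null: the smoothed spacing
abundances are permuted with respect to their spacing intervals, and the
autocorrelation and fit are recomputed.  Each permutation yields a fresh
pseudo-random series with its own σ, so the null distribution is nearly
identical across genomes (mean GdF ≈ 7, sd ≈ 0.8 for every genome we
simulate) — which is what makes a single GdF threshold transferable between
genomes.  Both a Gaussian-summary p-value and the empirical quantile are
reported.  Two properties of this null are worth knowing.  First, the
Gaussian summary is an approximation: the permutation distribution has a
mild positive skew (~0.3).  Second, the genuine series carries short-range
serial correlation inherited from the 3-bp sliding smoothing, which
permutation destroys; the genuine GdF of a non-periodic genome is therefore,
if anything, *inflated* relative to the null, making the significance call
conservative.

### Variance of the period

Spacings are assigned round-robin, in discovery order, to 1000 subsets at
collation time.  A bootstrap iterate draws 1000 subsets with replacement,
sums them, and re-runs smoothing, autocorrelation and the fit; the spread of
the resampled periods estimates the sampling variance of the period.  The
variance is insensitive to the subset count for ~50 or more subsets (we
verify 50 vs 1000 agree within 20%), and scales like n<sup>−1/2</sup> in the
number of spacings.  Motif periods are compared to the genomic period with a
Welch two-sample t-test on the bootstrap distributions (the bootstrap sds of
individual motifs differ, so the unequal-variance form is the safe reading),
and the hypothesis of a single genome-wide period is examined by normalizing
each significantly periodic motif's period as (λᵢ − λ_genomic)/sdᵢ and
testing against a *fully specified* standard normal (no parameter
estimation, since the normalization already standardizes).

### Fragment scans and catenation rescue

To ask whether periodicity is a property of the whole chromosome or of a few
loci, random fragments are scanned: the spacings of the strongly periodic
motif sets (GdF < 1.5 and amplitude > 0.2, both strict) are pooled within
each fragment and fitted over periods within ±5 bp of the genomic period.
Fragments are classified "genomic" (within 0.6 bp of the genomic period),
"low-/high-extreme" (outermost 1-bp bands of the window) or "other".
Short fragments need an edge correction: at fragment length *L* there are
only *L*−1−*d* start-pair opportunities at spacing *d*, a linear trend that
would otherwise leak a positive baseline into the autocorrelation; counts
are rescaled by (*L*−1)/(*L*−1−*d*).  Whole-genome fits leave the trend
uncorrected, where it is below 0.1%.  Catenation pools the spacing
histograms of 2–5 non-overlapping weak fragments — histogram summation
rather than literal sequence concatenation, so no spurious junction
spacings are created — and refits; a shared underlying period that is too
weak to detect per fragment becomes detectable in the pool.

### Cross-genome comparison

Per-genome profiles record GdF, amplitude and strength (ln(GdF/A)) of each
of the 55 motif sets, fitted with the period held at the genomic period.
Profiles are compared by Pearson correlation of GdF values; regression lines
between two noisy GdF axes use Deming regression with error-variance ratio 1
(both axes carry the same statistic, so orthogonal regression is the
symmetric choice).  Pairwise period differences exclude genomes whose
genomic fit is not significant.  Frequencies of periodicity across taxa are
estimated by drawing one genome per genus (or family) per iteration, 1500
iterations by default, reporting the mean and sd of the per-set frequencies.
GC-content confounding in relatedness comparisons is handled by histogram
matching of the |ΔGC| distributions across relatedness classes with 1%-wide
bins.  When comparing strength of periodicity between genomes of different
sizes, histograms can be down-sampled to a common spacing count with a
without-replacement (hypergeometric) subsample.

## Synthetic genomes

The generators are first-class, tested code; they define the conditions
under which the pipeline is verified.

**Planted genomes.**  Anchor *j* of a lattice of pitch λ sits at
round(*j*·λ + *W*ⱼ), where *W* is a Gaussian random walk with step sd
`jitter`.  Rounding the accumulated fractional pitch keeps the mean pitch
exactly λ; the *cumulative* jitter emulates the phase drift that indels
impose, so the planted autocorrelation decays exponentially just as the
damped-sine model assumes (half-life ≈ ln 2·λ³/(2π²·jitter²) ≈ 40 bp at
λ = 10.5, jitter = 1 — i.i.d. jitter instead would produce a non-decaying
signal outside the model family).  Anchors are thinned to the target
density, and motifs are written by overwriting background bases, so genome
length and spacings are exact.  Several motifs can be planted at one shared
period on independent lattices to emulate a genome in which a suite of
dinucleotides is periodic.  A truth sidecar records the period, positions
and settings.  What these genomes do *not* emulate: compositional
heterogeneity along the chromosome, gene structure interacting with the
motif lattice, and realistic amplitude — at the reference density of
3/100 bp the planted amplitude (~1.2) is several-fold stronger than real
genomes (~0.1–0.4), which makes recovery easier but pushes the absolute
GdF *up*, since the residual mismatch between a planted comb and a pure
damped cosine scales with amplitude.  Passing recovery tests on these
genomes therefore demonstrates correctness of the machinery, not
performance on any particular real genome.

**Random genomes** are i.i.d. sequences at a configurable GC content, the
no-signal null.

**Markov shuffles** re-emit a source genome from an order-3 chain whose
transition frequencies are estimated separately for each codon position of
the emitted base (and separately for intergenic stretches), with gene
lengths resampled from the source's gene-length distribution, strands drawn
at the source's strand bias, and unseen contexts backed off to order 2, 1,
then 0.  This preserves codon-position-specific dinucleotide, trinucleotide
and tetranucleotide frequencies, gene lengths and strand bias while
destroying any long-range spacing structure — a composition-matched,
periodicity-free null.  The sampler conditions each base's transition table
on the codon position of the base being emitted, the simplest reading of
"codon-position-specific frequencies"; intergenic emission is unconditioned.

## Numerical choices and degenerate inputs

* Coordinates are 1-based closed intervals throughout (R convention).
* Replicons are treated as linear strings; spacings across the FASTA
  junction (≤202 bp of a multi-Mb molecule) are ignored.  Replicore mode
  wraps at the sequence end so each arm is contiguous.
* Constant or zero-variance spacing series are an error (autocorrelation is
  undefined); an amplitude of zero makes the strength undefined and it is
  reported as `NA` rather than raised.
* Multi-record FASTA files keep the largest replicon by default.
* All randomized procedures accept a `seed` argument and restore the
  caller's RNG state.

## Problem sizes used by the test suite

The suite verifies the pipeline on synthetic genomes of 100–600 kb
(500 kb for period-recovery, 120–150 kb for the 120-genome null-calibration
panel, 400 kb for fragment/catenation studies with 8-kb fragments, and
240/120 kb with 150 bootstrap iterates for the variance scaling checks).
These sizes were chosen so that each property is measured well inside the
regime where its expected behavior holds, while the whole suite remains
quick to run; the corresponding tests assert the measured behavior
(period-recovery error within 0.05 bp, a null false-positive rate of at most
5% over the 120-genome panel, and a bootstrap sd ratio near the square root
of two for halved data).

## Known limitations

* The damped sine models a single period; genomes with genuinely mixed
  periods are flagged by the normality test rather than fitted.
* GdF is an absolute misfit measure: a very strong signal whose shape
  deviates from a damped cosine can exceed the GdF threshold even though its
  period is measured precisely (see the planted-genome note above).
* The fragment edge correction assumes homogeneous composition within a
  fragment; strong local composition gradients can still tilt short-fragment
  histograms.
* The Markov shuffler requires gene models with frames; genomes without
  annotation cannot be shuffled codon-aware.
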