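# Shared fixtures, built once per test run and cached across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# a 400-kb genome with a strongly periodic planted AA motif and its genomic fit
planted_strong <- function() {
  fixture("planted_strong", function() {
    g <- planted_genome(4e5, period = 10.5, density = 3, jitter = 1, seed = 11)
    fit <- period_fit(g$sequence)
    list(genome = g, fit = fit)
  })
}

# its per-motif-set profile at the genomic period
planted_profile <- function() {
  fixture("planted_profile", function() {
    ps <- planted_strong()
    gdf_profile(ps$genome$sequence, genomic = ps$fit)
  })
}

# smoothed spacing series and autocorrelation of the strong planted genome
planted_autocorr <- function() {
  planted_strong()$fit$autocorr
}

# codon-position-specific tetranucleotide frequencies of coding regions,
# one 256-column row per codon position class of the emitted base
codon_tetra_freqs <- function(g) {
  codes <- periodscope:::encode_bases(g$sequence)
  codes[is.na(codes)] <- 1L
  comp <- c(4L, 3L, 2L, 1L)
  counts <- matrix(0, nrow = 3, ncol = 256)
  for (i in seq_len(nrow(g$genes))) {
    seg <- codes[g$genes$start[i]:g$genes$end[i]]
    if (g$genes$strand[i] == "-") seg <- rev(comp[seg])
    n <- length(seg)
    if (n < 4L) next
    cls <- periodscope:::cds_codon_positions(n, g$genes$frame[i])[4:n]
    idx <- (seg[1:(n - 3)] - 1L) * 64L + (seg[2:(n - 2)] - 1L) * 16L +
      (seg[3:(n - 1)] - 1L) * 4L + seg[4:n]
    for (cl in 1:3) {
      tb <- tabulate(idx[cls == cl], nbins = 256)
      counts[cl, ] <- counts[cl, ] + tb
    }
  }
  sweep(counts, 1, rowSums(counts), "/")
}

total_variation <- function(p, q) sum(abs(p - q)) / 2
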