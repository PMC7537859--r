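Package: periodscope
Title: Robust Measurement of Dinucleotide Periodicity in Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Measures the periodic spacing of degenerate dinucleotide motifs in
    genome sequences. Occurrences of the 100 dinucleotides over the IUPAC
    symbols G, A, T, C, R, Y, W, S, M and K are located, start-to-start
    spacings up to 202 bp are collated and smoothed over three bases, and a
    damped sine curve is fitted to the autocorrelation of the spacing
    abundances by a coarse-then-refined grid search.  Significance of the fit
    is judged by a permutation null on the autocorrelations, the variance of
    the period by a 1000-subset bootstrap, and fragment-level scans, motif-set
    periodicity profiles, cross-genome comparisons and synthetic-genome
    generators (planted-period, uniform random, and codon-structure-preserving
    Markov shuffles) support verification and comparative analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    nortest,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
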