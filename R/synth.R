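# Synthetic genomes: uniform random backgrounds, planted-period genomes with
# truth sidecars, synthetic gene models, and codon-structure-preserving
# Markov shuffles used as periodicity-free null genomes.

#' Uniform random genome
#'
#' Bases drawn i.i.d. at the requested GC content.
#'
#' @param length Genome length (bp).
#' @param gc GC fraction in (0, 1).
#' @param seed Optional seed (caller's RNG state is preserved).
#' @return Sequence string.
#' @export
random_genome <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length > 0, gc > 0, gc < 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G T
  with_seed(seed,
    decode_bases(sample.int(4L, length, replace = TRUE, prob = p)))
}

#' Genome with a planted periodic motif
#'
#' Writes concrete instances of a (possibly degenerate) dinucleotide motif
#' onto an i.i.d. background at positions taken from an anchor lattice of
#' pitch `period`: anchor j sits at `round(j * period + W_j)`, where `W` is a
#' Gaussian random walk with step standard deviation `jitter`.  Fractional
#' periods accumulate exactly (the mean pitch equals `period`), and the
#' cumulative jitter emulates the phase drift that small insertions and
#' deletions impose on real genomes, so the autocorrelation of the planted
#' signal decays exponentially with lag just as the damped-sine model
#' assumes (half-life roughly `ln(2) * period^3 / (2 * pi^2 * jitter^2)`).
#' Anchors are thinned to the target density.  Motifs are written by
#' overwriting background bases (not insertion), so the genome length is
#' exact and spacings are controlled.
#'
#' @param length Genome length (bp).
#' @param period Planted period lambda (bp), > 2.
#' @param motif Degenerate dinucleotide(s); each occurrence is instantiated
#'   as a uniformly chosen concrete base pair consistent with the pattern.
#'   Several motifs (with per-motif densities) may be planted at the same
#'   period on independent lattices, emulating a genome in which a suite of
#'   dinucleotides shares one genomic period.
#' @param density Expected motif instances per 100 bp (recycled over
#'   `motif`).
#' @param jitter Step standard deviation (bp) of the cumulative Gaussian
#'   positional jitter (indel-like phase drift).
#' @param gc Background GC fraction.
#' @param seed Optional seed (caller's RNG state is preserved).
#' @return List with `sequence` and a `truth` sidecar recording `period`,
#'   `motif`, the written `positions`, `density`, `jitter`, `gc`, `seed`
#'   and `length`.
#' @export
planted_genome <- function(length, period, motif = "AA", density = 3,
                           jitter = 1, gc = 0.5, seed = NULL) {
  stopifnot(length > 0, period > 2, all(density > 0), gc > 0, gc < 1)
  .check_pattern(motif)
  len <- as.integer(length); rm(length)
  density <- rep_len(density, base::length(motif))
  keep_prob <- density * period / 100
  if (any(keep_prob > 1))
    stop("density ", max(density), "/100 bp exceeds the lattice capacity at ",
         "period ", period, call. = FALSE)
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    codes <- sample.int(4L, len, replace = TRUE, prob = p)
    n_anchor <- floor((len - 1) / period)
    positions <- vector("list", base::length(motif))
    for (im in seq_along(motif)) {
      drift <- cumsum(stats::rnorm(n_anchor, 0, jitter))
      anchors <- round(seq_len(n_anchor) * period + drift)
      pos <- anchors[stats::runif(n_anchor) < keep_prob[im]]
      pos <- pmin(pmax(pos, 1L), len - 1L)
      if (length(pos) > 0 &&
          1 - length(unique(pos)) / length(pos) > 0.5)
        stop("more than half of the planted positions collide; ",
             "reduce density or jitter", call. = FALSE)
      n <- length(pos)
      m1 <- .iupac_match[[substr(motif[im], 1L, 1L)]]
      m2 <- .iupac_match[[substr(motif[im], 2L, 2L)]]
      codes[pos] <- m1[sample.int(length(m1), n, replace = TRUE)]
      codes[pos + 1L] <- m2[sample.int(length(m2), n, replace = TRUE)]
      positions[[im]] <- sort(unique(pos))
    }
    list(sequence = decode_bases(codes),
         truth = list(period = period, motif = motif,
                      positions = if (base::length(motif) == 1L)
                        positions[[1L]] else positions,
                      density = density, jitter = jitter, gc = gc,
                      seed = seed, length = len))
  })
}

#' Synthetic gene models
#'
#' Tiles a genome with non-overlapping gene intervals (lengths a multiple of
#' three) separated by intergenic gaps, with a configurable strand bias.
#' Used to exercise codon-position filtering and as annotation for source
#' genomes of the Markov shuffler.
#'
#' @param length Genome length (bp).
#' @param mean_gene Mean gene length (bp); lengths are gamma-distributed,
#'   rounded to multiples of 3, minimum 90 bp.
#' @param mean_gap Mean intergenic gap (bp), geometric.
#' @param plus_fraction Fraction of genes on the plus strand.
#' @param seed Optional seed (caller's RNG state is preserved).
#' @return Gene-model data frame (`start`, `end`, `strand`, `frame`).
#' @export
synthetic_genes <- function(length, mean_gene = 900, mean_gap = 120,
                            plus_fraction = 0.55, seed = NULL) {
  len <- as.integer(length); rm(length)
  with_seed(seed, {
    rows <- list()
    pos <- 1L
    repeat {
      gap <- stats::rgeom(1L, 1 / mean_gap)
      glen <- max(90L, 3L * round(stats::rgamma(1L, shape = 4,
                                                scale = mean_gene / 4) / 3))
      start <- pos + gap
      end <- start + glen - 1L
      if (end > len) break
      rows[[length(rows) + 1L]] <- data.frame(
        start = start, end = end,
        strand = if (stats::runif(1L) < plus_fraction) "+" else "-",
        frame = 0L, stringsAsFactors = FALSE)
      pos <- end + 1L
    }
    do.call(rbind, rows)
  })
}

# codon position (1,2,3) for each base of a coding-strand CDS with the given
# frame (phase: bases to skip before the first complete codon)
cds_codon_positions <- function(n, frame = 0L) {
  ((seq_len(n) - 1L - frame) %% 3L) + 1L
}

# order-3 transition tables conditioned on context class
# classes: 1,2,3 = codon position of the emitted base; 4 = intergenic
estimate_markov <- function(g) {
  codes <- encode_bases(g$sequence)
  codes[is.na(codes)] <- sample.int(4L, sum(is.na(codes)), replace = TRUE)
  genes <- g$genes[order(g$genes$start), , drop = FALSE]
  counts <- numeric(4L * 64L * 4L)   # [class, context, base]
  starts_coding <- list()
  starts_inter <- list()
  add_segment <- function(seg, cls) {
    n <- length(seg)
    if (n < 4L) return()
    ctx <- (seg[1:(n - 3L)] - 1L) * 16L + (seg[2:(n - 2L)] - 1L) * 4L +
      (seg[3:(n - 1L)] - 1L)
    idx <- ((cls[4:n] - 1L) * 64L + ctx) * 4L + (seg[4:n] - 1L) + 1L
    tb <- tabulate(idx, nbins = 4L * 64L * 4L)
    counts <<- counts + tb
  }
  comp <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G on codes A=1,C=2,G=3,T=4
  gene_lengths <- genes$end - genes$start + 1L
  # coding segments on the coding strand
  for (i in seq_len(nrow(genes))) {
    seg <- codes[genes$start[i]:genes$end[i]]
    if (genes$strand[i] == "-") seg <- rev(comp[seg])
    cls <- cds_codon_positions(length(seg), genes$frame[i])
    add_segment(seg, cls)
    if (length(seg) >= 3L)
      starts_coding[[length(starts_coding) + 1L]] <- seg[1:3]
  }
  # intergenic stretches
  gstart <- c(genes$start, g$length + 1L)
  prev_end <- c(0L, genes$end)
  for (i in seq_along(gstart)) {
    from <- prev_end[i] + 1L
    to <- gstart[i] - 1L
    if (to < from) next
    seg <- codes[from:to]
    add_segment(seg, rep(4L, length(seg)))
    if (length(seg) >= 3L)
      starts_inter[[length(starts_inter) + 1L]] <- seg[1:3]
  }
  # counts index was ((class-1)*64 + ctx)*4 + base: base fastest, then
  # context, then class
  arr <- array(counts, dim = c(4L, 64L, 4L))
  # back off unseen contexts to order 2, then 1, then 0
  n_backoff <- 0L
  probs <- array(0, dim = c(4L, 64L, 4L))
  for (cl in 1:4) {
    tab <- arr[, , cl]                       # 4 x 64 (base x context)
    tot <- colSums(tab)
    c2 <- t(rowsum(t(tab), (0:63) %% 16L))   # 4 x 16 over last two bases
    c1 <- t(rowsum(t(tab), (0:63) %% 4L))    # 4 x 4 over last base
    c0 <- rowSums(tab)
    for (j in 1:64) {
      v <- tab[, j]
      if (tot[j] == 0) {
        n_backoff <- n_backoff + 1L
        v <- c2[, (j - 1L) %% 16L + 1L]
        if (sum(v) == 0) v <- c1[, (j - 1L) %% 4L + 1L]
        if (sum(v) == 0) v <- c0
        if (sum(v) == 0) v <- rep(1, 4L)
      }
      probs[, j, cl] <- v / sum(v)
    }
  }
  if (n_backoff > 0L)
    message("markov_genome: ", n_backoff,
            " unseen context(s) backed off to lower order")
  as_pool <- function(lst) {
    if (length(lst)) do.call(rbind, lst)
    else matrix(sample.int(4L, 3L, replace = TRUE), nrow = 1L)
  }
  list(probs = probs, gene_lengths = gene_lengths,
       gaps = pmax(genes$start - c(0L, genes$end[-nrow(genes)]) - 1L, 0L),
       plus_fraction = mean(genes$strand != "-"),
       starts3 = list(coding = as_pool(starts_coding),
                      inter = as_pool(starts_inter)))
}

#' Codon-structure-preserving shuffled genome
#'
#' Emits an artificial genome from an order-3 Markov chain estimated on a
#' source genome, with transition frequencies conditioned on the codon
#' position of the emitted base (so codon-position-specific dinucleotide,
#' trinucleotide and tetranucleotide frequencies are preserved), gene lengths
#' resampled from the source's gene-length distribution, strands assigned
#' with the source's strand bias, and intergenic stretches emitted from
#' intergenic frequencies.  The result preserves local composition but
#' carries no planted periodicity, so it serves as a realistic null genome.
#'
#' @param g Source [genome_record()] with gene models (frames required).
#' @param length Target genome length (bp); defaults to the source length.
#' @param seed Optional seed (caller's RNG state is preserved).
#' @param model Optional precomputed model from a previous call (attribute
#'   `model` of a result), to amortize estimation across replicate genomes.
#' @return A [genome_record()] with the emitted gene models; the estimated
#'   model is attached as attribute `model`.
#' @export
markov_genome <- function(g, length = NULL, seed = NULL, model = NULL) {
  stopifnot(inherits(g, "genome_record"))
  if (is.null(g$genes) || nrow(g$genes) == 0L)
    stop("source genome has no gene models", call. = FALSE)
  target <- as.integer(if (is.null(length)) g$length else length)
  rm(length)
  if (is.null(model)) model <- estimate_markov(g)
  # cumulative transition matrix rows: class*64 + context (0-based)
  cum <- matrix(0, nrow = 4L * 64L, ncol = 4L)
  for (cl in 1:4) for (j in 1:64)
    cum[(cl - 1L) * 64L + j, ] <- cumsum(model$probs[, j, cl])
  comp <- c(4L, 3L, 2L, 1L)
  emit_segment <- function(n, cls0, start_pool) {
    init <- start_pool[sample.int(nrow(start_pool), 1L), ]
    if (n <= 3L) return(init[seq_len(n)])
    cls <- if (cls0 == 4L) rep(3L, n) else (cds_codon_positions(n) - 1L)
    body <- emit_markov(n - 3L, init - 1L, cum, cls[4:n],
                        stats::runif(n - 3L)) + 1L
    c(init, body)
  }
  with_seed(seed, {
    pieces <- list()
    genes <- list()
    total <- 0L
    while (total < target) {
      gap <- sample(model$gaps, 1L)
      if (gap > 0L) {
        pieces[[length(pieces) + 1L]] <- emit_segment(gap, 4L,
                                                      model$starts3$inter)
        total <- total + gap
      }
      glen <- sample(model$gene_lengths, 1L)
      if (total + glen > target) break
      seg <- emit_segment(glen, 1L, model$starts3$coding)
      strand <- if (stats::runif(1L) < model$plus_fraction) "+" else "-"
      if (strand == "-") seg <- rev(comp[seg])
      genes[[length(genes) + 1L]] <- data.frame(
        start = total + 1L, end = total + glen, strand = strand,
        frame = 0L, stringsAsFactors = FALSE)
      pieces[[length(pieces) + 1L]] <- seg
      total <- total + glen
    }
    if (total < target)
      pieces[[length(pieces) + 1L]] <-
        emit_segment(target - total, 4L, model$starts3$inter)
    out <- unlist(pieces, use.names = FALSE)[seq_len(target)]
    res <- genome_record(decode_bases(out),
                         id = paste0(g$id, "_markov_shuffle"),
                         genes = do.call(rbind, genes))
    attr(res, "model") <- model
    res
  })
}
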