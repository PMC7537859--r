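# Motif scanning and spacing-histogram construction.
#
# Spacings are start-to-start distances between ALL ordered pairs of
# occurrences of a pattern up to `max_spacing` bp apart (not just adjacent
# occurrences), so enrichment is visible at every multiple of the period and
# the histogram does not depend on intervening occurrences.

new_spacing_histogram <- function(counts, max_spacing, subsets = NULL) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == max_spacing)
  structure(list(counts = counts, max_spacing = as.integer(max_spacing),
                 n_spacings = sum(counts), subsets = subsets),
            class = "spacing_histogram")
}

#' @export
print.spacing_histogram <- function(x, ...) {
  cat("<spacing_histogram> spacings 1..", x$max_spacing, " bp, ",
      format(x$n_spacings, big.mark = ","), " spacings",
      if (!is.null(x$subsets)) paste0(", ", nrow(x$subsets), " subsets"),
      "\n", sep = "")
  invisible(x)
}

#' Scan a sequence for a degenerate dinucleotide
#'
#' Finds every (possibly overlapping) occurrence of a degenerate dinucleotide
#' on the given strand.  Ambiguous bases in the sequence (N and friends) never
#' match any pattern symbol.
#'
#' @param x A [genome_record()] or sequence string.
#' @param pattern Two-symbol degenerate dinucleotide.
#' @param region Optional `c(from, to)` 1-based interval; matches must lie
#'   entirely inside it.
#' @return Strictly increasing integer vector of 1-based start positions.
#' @examples
#' scan_pattern("AATAA", "AA")  # 1, 4
#' scan_pattern("AATAA", "WW")  # 1, 2, 3, 4
#' @export
scan_pattern <- function(x, pattern, region = NULL) {
  codes <- dinuc_codes(encode_bases(as_sequence(x)))
  pos <- which(codes %in% pattern_match_codes(pattern))
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1L] >= 1L,
              region[2L] <= length(codes) + 1L)
    pos <- pos[pos >= region[1L] & pos + 1L <= region[2L]]
  }
  as.integer(pos)
}

#' Collate spacings between motif occurrences
#'
#' Counts the start-to-start distances between all ordered pairs of positions
#' up to `max_spacing` bp apart.  When `subsets` is given, each spacing is
#' assigned round-robin (in discovery order: first position ascending, then
#' second) to one of `subsets` sub-histograms; bootstrap resampling draws
#' these subsets with replacement.
#'
#' @param positions Sorted increasing occurrence start positions.
#' @param max_spacing Largest spacing collated (bp); 202 so that 3-bp
#'   smoothing reports spacings up to 200.
#' @param subsets Number of round-robin subsets to record, or `NULL` for none.
#' @return A `spacing_histogram`.
#' @examples
#' h <- collate_spacings(c(0, 11, 22))
#' h$counts[c(11, 22)]  # 2, 1
#' @export
collate_spacings <- function(positions, max_spacing = 202L, subsets = NULL) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing", call. = FALSE)
  n_pairs <- if (length(positions))
    sum(findInterval(positions + max_spacing, positions) -
          seq_along(positions)) else 0
  if (n_pairs > 1e8)
    stop("more than 1e8 spacings; subsample positions or use ",
         "pooled_spacings() on the sequence", call. = FALSE)
  d <- pair_spacings(positions, as.integer(max_spacing))
  counts <- tabulate(d, nbins = max_spacing)
  sub <- NULL
  if (!is.null(subsets)) {
    k <- as.integer(subsets)
    if (k < 1L) stop("subsets must be >= 1", call. = FALSE)
    grp <- (seq_along(d) - 1L) %% k
    sub <- matrix(tabulate(d + max_spacing * grp, nbins = max_spacing * k),
                  nrow = k, ncol = max_spacing, byrow = TRUE)
  }
  new_spacing_histogram(counts, max_spacing, subsets = sub)
}

# 256 x max_spacing dinucleotide pair-count table for a sequence
pair_count_table <- function(codes, max_spacing = 202L) {
  dinuc_pair_counts(codes, as.integer(max_spacing))
}

# spacing counts for a weighted pattern collection from a pair-count table
counts_from_table <- function(tab, weights) {
  as.numeric(crossprod(tab, weights))
}

#' Pooled spacing histogram over a pattern collection
#'
#' Element-wise sum of the per-pattern spacing histograms; with the default
#' pattern list this is the all-dinucleotide pooled histogram from which the
#' genomic period is estimated.  Overlap between degenerate patterns is
#' intentionally counted multiply, as every dinucleotide contributes its own
#' spacings.
#'
#' @param x A [genome_record()] or sequence string.
#' @param patterns Character vector of degenerate dinucleotides (default: all
#'   100).
#' @param max_spacing Largest spacing collated (bp).
#' @return A `spacing_histogram` (without subset partition).
#' @export
pooled_spacings <- function(x, patterns = dinucleotide_patterns(),
                            max_spacing = 202L) {
  codes <- dinuc_codes(encode_bases(as_sequence(x)))
  tab <- pair_count_table(codes, max_spacing)
  new_spacing_histogram(counts_from_table(tab, pattern_weight_vector(patterns)),
                        max_spacing)
}

#' Smooth a spacing histogram over three bases
#'
#' Averages the raw counts over a forward sliding 3-bp window to remove the
#' three-base periodicity imparted by the genetic code: the value reported at
#' spacing s is the mean of the counts at s, s+1 and s+2 (so the value at
#' 200 bp averages the counts at 200, 201 and 202 bp).  Spacings below 6 bp
#' are discarded to reduce the impact of homopolymeric repeats.
#'
#' @param h A `spacing_histogram` with `max_spacing >= 8`.
#' @param min_spacing First reported spacing (bp).
#' @return A named numeric vector (class `smoothed_series`) over spacings
#'   `min_spacing` to `max_spacing - 2`.
#' @export
smooth_spacings <- function(h, min_spacing = 6L) {
  stopifnot(inherits(h, "spacing_histogram"), h$max_spacing >= min_spacing + 2L)
  smooth_counts(h$counts, h$max_spacing, min_spacing)
}

smooth_counts <- function(counts, max_spacing, min_spacing = 6L) {
  s <- min_spacing:(max_spacing - 2L)
  v <- (counts[s] + counts[s + 1L] + counts[s + 2L]) / 3
  structure(v, names = s, spacings = s, class = "smoothed_series")
}

#' @export
print.smoothed_series <- function(x, ...) {
  s <- attr(x, "spacings")
  cat("<smoothed_series> spacings ", s[1L], "..", s[length(s)],
      " bp (3-bp sliding mean)\n", sep = "")
  print(unclass(x)[seq_len(min(10L, length(x)))])
  if (length(x) > 10L) cat("...\n")
  invisible(x)
}

#' Subsample a spacing histogram
#'
#' Uniform random subsample of spacings without replacement, used to equalize
#' the total numbers of spacings when comparing the strength of periodicity
#' between genomes of different lengths.
#'
#' @param h A `spacing_histogram`.
#' @param n_total Number of spacings to keep (`<= h$n_spacings`).
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return A `spacing_histogram` (subset partition, if any, is dropped).
#' @export
subsample_spacings <- function(h, n_total, seed = NULL) {
  stopifnot(inherits(h, "spacing_histogram"))
  if (n_total > h$n_spacings)
    stop("n_total exceeds the available ", h$n_spacings, " spacings",
         call. = FALSE)
  with_seed(seed, {
    counts <- h$counts
    out <- numeric(length(counts))
    left <- n_total
    rest <- sum(counts)
    for (i in seq_along(counts)) {
      rest <- rest - counts[i]
      x <- if (left > 0 && counts[i] > 0)
        stats::rhyper(1L, counts[i], rest, left) else 0
      out[i] <- x
      left <- left - x
    }
    new_spacing_histogram(out, h$max_spacing)
  })
}

#' Annotate occurrence positions with codon positions
#'
#' For each occurrence start position, finds the covering gene (if any) and
#' the codon position (1, 2 or 3) of that base given the gene's strand and
#' frame; positions outside genes get `NA`.
#'
#' @param positions Occurrence start positions (1-based).
#' @param genes Gene-model data frame (`start`, `end`, `strand`, `frame`).
#' @return Data frame with columns `position`, `gene` (row index into `genes`
#'   or `NA`) and `codon_pos`.
#' @export
annotate_codon_positions <- function(positions, genes) {
  if (is.null(genes)) stop("gene models are required", call. = FALSE)
  genes <- genes[order(genes$start), , drop = FALSE]
  gi <- findInterval(positions, genes$start)
  inside <- gi >= 1L & positions <= genes$end[pmax(gi, 1L)]
  gene <- ifelse(inside, gi, NA_integer_)
  cp <- rep(NA_integer_, length(positions))
  ok <- which(inside)
  if (length(ok)) {
    gs <- genes$start[gene[ok]]; ge <- genes$end[gene[ok]]
    fr <- genes$frame[gene[ok]]; st <- genes$strand[gene[ok]]
    plus <- st != "-"
    cp[ok] <- ifelse(plus,
                     ((positions[ok] - gs - fr) %% 3L) + 1L,
                     ((ge - positions[ok] - fr) %% 3L) + 1L)
  }
  data.frame(position = positions, gene = gene, codon_pos = cp)
}

#' Collate spacings with a codon-position exclusion rule
#'
#' Like [collate_spacings()], but drops spacing pairs whose two occurrences
#' lie in the same gene at the excluded (unordered) pair of codon positions.
#' Used to test whether repeated protein motifs, rather than genuine genomic
#' periodicity, drive the signal: e.g. excluding pairs at codon positions 1
#' and 2 within one gene.
#'
#' @param positions Sorted occurrence start positions.
#' @param genes Gene-model data frame.
#' @param exclude Unordered codon-position pair to drop, e.g. `c(1, 2)`, or
#'   `NULL` for no filtering.
#' @param max_spacing Largest spacing collated (bp).
#' @return A `spacing_histogram`.
#' @export
codon_filtered_spacings <- function(positions, genes, exclude = c(1L, 2L),
                                    max_spacing = 202L) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing", call. = FALSE)
  n <- length(positions)
  m <- findInterval(positions + max_spacing, positions) - seq_len(n)
  if (sum(m) > 5e7)
    stop("too many spacing pairs for codon-position filtering; ",
         "restrict the region", call. = FALSE)
  i <- rep.int(seq_len(n), m)
  j <- i + sequence(m)
  d <- positions[j] - positions[i]
  if (!is.null(exclude)) {
    ann <- annotate_codon_positions(positions, genes)
    same_gene <- !is.na(ann$gene[i]) & !is.na(ann$gene[j]) &
      ann$gene[i] == ann$gene[j]
    ex <- sort(as.integer(exclude))
    drop <- same_gene &
      pmin(ann$codon_pos[i], ann$codon_pos[j]) == ex[1L] &
      pmax(ann$codon_pos[i], ann$codon_pos[j]) == ex[2L]
    d <- d[!drop]
  }
  new_spacing_histogram(tabulate(d, nbins = max_spacing), max_spacing)
}
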