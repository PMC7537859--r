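test_that("scanning finds overlapping degenerate matches and skips ambiguity codes", {
  expect_identical(scan_pattern("AATAA", "AA"), c(1L, 4L))
  expect_identical(scan_pattern("AATAA", "WW"), 1:4)
  expect_identical(scan_pattern("AATAA", "SS"), integer(0))
  expect_identical(scan_pattern("", "AA"), integer(0))
  expect_identical(scan_pattern("ANAAA", "AA"), c(3L, 4L))
  expect_identical(scan_pattern("AATAA", "AA", region = c(2, 5)), 4L)
})

test_that("scanning agrees with Biostrings IUPAC matching on ACGTN sequences", {
  set.seed(71)
  chars <- sample(c("A", "C", "G", "T", "N"), 2000, replace = TRUE,
                  prob = c(.24, .24, .24, .24, .04))
  s <- paste(chars, collapse = "")
  for (p in c("AA", "WW", "RY", "GC", "AK", "SM")) {
    ref <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(p), Biostrings::DNAString(s), fixed = "subject"))
    expect_identical(scan_pattern(s, p), as.integer(ref), label = p)
  }
})

test_that("scan positions mirror under reverse complementation of the sequence", {
  s <- random_genome(3000, seed = 9)
  rs <- revcomp_sequence(s)
  L <- nchar(s)
  for (p in c("GA", "WR", "GC", "AK")) {
    expect_identical(scan_pattern(s, pattern_revcomp(p)),
                     sort(L - scan_pattern(rs, p)), label = p)
    # and the spacing histograms from the two scans coincide
    h1 <- collate_spacings(scan_pattern(s, pattern_revcomp(p)))
    h2 <- collate_spacings(scan_pattern(rs, p))
    expect_equal(h1$counts, h2$counts, label = p)
  }
})

test_that("spacing collation counts all ordered pairs within the window", {
  h <- collate_spacings(c(0L, 11L, 22L))
  expect_equal(h$counts[11], 2)
  expect_equal(h$counts[22], 1)
  expect_equal(h$n_spacings, 3)
  expect_equal(sum(h$counts), 3)
  expect_equal(collate_spacings(5L)$n_spacings, 0)
  # brute-force all-pairs oracle
  set.seed(12)
  for (rep in 1:3) {
    pos <- sort(sample.int(4000, 300))
    oracle <- numeric(202)
    for (i in seq_along(pos)) for (j in seq_along(pos)) {
      d <- pos[j] - pos[i]
      if (i < j && d <= 202) oracle[d] <- oracle[d] + 1
    }
    expect_equal(collate_spacings(pos)$counts, oracle)
  }
  expect_error(collate_spacings(c(3L, 1L)), "increasing")
})

test_that("round-robin subsets conserve the histogram and are deterministic", {
  set.seed(33)
  pos <- sort(sample.int(5000, 400))
  h <- collate_spacings(pos, subsets = 1000)
  expect_equal(colSums(h$subsets), h$counts)
  totals <- rowSums(h$subsets)
  expect_lte(max(totals) - min(totals), 1)
  h2 <- collate_spacings(pos, subsets = 1000)
  expect_identical(h$subsets, h2$subsets)
  # fewer spacings than subsets: one spacing per nonempty subset
  h3 <- collate_spacings(c(1L, 500L, 1000L, 1500L, 2000L), subsets = 1000)
  expect_equal(sum(rowSums(h3$subsets) > 0), h3$n_spacings)
  expect_true(all(rowSums(h3$subsets) <= 1))
})

test_that("3-bp smoothing averages forward windows over spacings 6..200", {
  counts <- numeric(202)
  counts[200] <- 3; counts[201] <- 6; counts[202] <- 0
  h <- periodscope:::new_spacing_histogram(counts, 202)
  v <- smooth_spacings(h)
  expect_length(v, 195L)
  expect_equal(unname(v["200"]), 3)
  expect_equal(attr(v, "spacings"), 6:200)
  # constant series is unchanged
  hc <- periodscope:::new_spacing_histogram(rep(7, 202), 202)
  expect_equal(as.numeric(smooth_spacings(hc)), rep(7, 195))
  # random histogram matches direct 3-term means
  set.seed(4)
  counts <- rpois(202, 50)
  h <- periodscope:::new_spacing_histogram(counts, 202)
  v <- smooth_spacings(h)
  s <- 6:200
  expect_equal(as.numeric(v), (counts[s] + counts[s + 1] + counts[s + 2]) / 3)
})

test_that("pooled histograms are element-wise sums of per-pattern histograms", {
  s <- random_genome(6000, seed = 22)
  pats <- c("AA", "WR", "GC", "SS", "TY")
  per <- lapply(pats, function(p) collate_spacings(scan_pattern(s, p))$counts)
  pooled <- pooled_spacings(s, pats)
  expect_equal(pooled$counts, Reduce(`+`, per))
  one <- pooled_spacings(s, "WR")
  expect_equal(one$counts, collate_spacings(scan_pattern(s, "WR"))$counts)
  expect_equal(pooled$n_spacings, sum(vapply(per, sum, 0)))
})

test_that("replicores split into two contiguous arcs covering the chromosome", {
  s <- random_genome(10000, seed = 5)
  g <- genome_record(s, origin = 1L, terminus = 5001L)
  arms <- split_replicores(g)
  expect_equal(arms$right$length + arms$left$length, g$length)
  expect_identical(arms$right$sequence, substr(s, 1, 5000))
  expect_identical(arms$left$sequence, substr(s, 5001, 10000))
  # wrap across the FASTA junction
  g2 <- genome_record(s, origin = 8001L, terminus = 3001L)
  arms2 <- split_replicores(g2)
  expect_identical(arms2$right$sequence,
                   paste0(substr(s, 8001, 10000), substr(s, 1, 3000)))
  expect_equal(arms2$right$length + arms2$left$length, g2$length)
  expect_error(split_replicores(genome_record(s)), "whole replicon")
})

test_that("subsampling spacings is hypergeometric and conserves the total", {
  set.seed(44)
  pos <- sort(sample.int(20000, 800))
  h <- collate_spacings(pos)
  expect_equal(subsample_spacings(h, h$n_spacings, seed = 1)$counts, h$counts)
  expect_equal(subsample_spacings(h, 0, seed = 1)$n_spacings, 0)
  half <- subsample_spacings(h, round(h$n_spacings / 2), seed = 2)
  expect_equal(half$n_spacings, round(h$n_spacings / 2))
  expect_true(all(half$counts <= h$counts))
  expect_error(subsample_spacings(h, h$n_spacings + 1), "exceeds")
  # mean of repeated subsamples scales counts by the sampling fraction
  means <- Reduce(`+`, lapply(1:200, function(i)
    subsample_spacings(h, round(h$n_spacings / 2))$counts)) / 200
  expect_lt(max(abs(means - h$counts / 2)), 3)
})

test_that("codon-position filtering drops only same-gene pairs at the excluded positions", {
  genes <- data.frame(start = c(1L, 31L), end = c(30L, 60L),
                      strand = c("+", "+"), frame = c(0L, 0L))
  # occurrences at codon positions: 1 (pos 1), 2 (pos 2), 1 (pos 4), gene 2 pos 31 (cp 1)
  pos <- c(1L, 2L, 4L, 31L)
  ann <- annotate_codon_positions(pos, genes)
  expect_equal(ann$codon_pos, c(1L, 2L, 1L, 1L))
  expect_equal(ann$gene, c(1L, 1L, 1L, 2L))
  unfiltered <- codon_filtered_spacings(pos, genes, exclude = NULL)
  filtered <- codon_filtered_spacings(pos, genes, exclude = c(1, 2))
  # pairs (1,2) and (2,4) are at codon positions {1,2} within gene 1: dropped
  expect_equal(unfiltered$n_spacings - filtered$n_spacings, 2)
  expect_equal(filtered$counts[1], 0)   # spacing 1 from (1,2) gone
  # pair (2,31) spans two genes at positions {2,1}: retained
  expect_equal(filtered$counts[29], 1)
  # minus-strand codon positions count from the gene end
  gm <- data.frame(start = 1L, end = 30L, strand = "-", frame = 0L)
  annm <- annotate_codon_positions(c(30L, 29L, 28L), gm)
  expect_equal(annm$codon_pos, c(1L, 2L, 3L))
  expect_error(codon_filtered_spacings(pos, NULL), "required")
})
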