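# Degenerate dinucleotide alphabet and complement algebra.

#' IUPAC symbols used for degenerate dinucleotides
#'
#' The ten single- and two-base IUPAC symbols over which dinucleotide patterns
#' are formed: G, A, T, C plus the six two-base degeneracies R (A/G), Y (C/T),
#' W (A/T), S (C/G), M (A/C) and K (G/T).
#'
#' @format Character vector of length 10.
#' @export
iupac_symbols <- c("G", "A", "T", "C", "R", "Y", "W", "S", "M", "K")

# complements in the same symbol order: G,A,T,C,R,Y,W,S,M,K -> C,T,A,G,Y,R,W,S,K,M
.iupac_complement <- c(G = "C", A = "T", T = "A", C = "G", R = "Y",
                       Y = "R", W = "W", S = "S", M = "K", K = "M")

# concrete base codes (A=1, C=2, G=3, T=4) denoted by each symbol
.iupac_match <- list(G = 3L, A = 1L, T = 4L, C = 2L,
                     R = c(1L, 3L), Y = c(2L, 4L), W = c(1L, 4L),
                     S = c(2L, 3L), M = c(1L, 2L), K = c(3L, 4L))

.check_pattern <- function(pattern) {
  if (!is.character(pattern) || any(nchar(pattern) != 2L))
    stop("patterns must be two-character strings", call. = FALSE)
  sym <- c(substr(pattern, 1L, 1L), substr(pattern, 2L, 2L))
  bad <- setdiff(unique(sym), iupac_symbols)
  if (length(bad))
    stop("pattern symbol(s) outside {G,A,T,C,R,Y,W,S,M,K}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(pattern)
}

#' Enumerate all degenerate dinucleotide patterns
#'
#' All 100 ordered two-symbol patterns over the ten IUPAC symbols, in
#' lexicographic order over the symbol order G, A, T, C, R, Y, W, S, M, K.
#'
#' @return Character vector of 100 two-letter patterns.
#' @examples
#' length(dinucleotide_patterns())  # 100
#' @export
dinucleotide_patterns <- function() {
  paste0(rep(iupac_symbols, each = 10L), rep(iupac_symbols, times = 10L))
}

#' Reverse complement of a degenerate dinucleotide
#'
#' The reverse complement of pattern `s1 s2` is `comp(s2) comp(s1)` under the
#' symbol complement table G/C, A/T, R/Y, W/W, S/S, M/K.
#'
#' @param pattern Character vector of two-symbol patterns.
#' @return Character vector of reverse-complemented patterns.
#' @examples
#' pattern_revcomp("GA")  # "TC"
#' pattern_revcomp("GC")  # "GC" (palindromic)
#' @export
pattern_revcomp <- function(pattern) {
  .check_pattern(pattern)
  s1 <- substr(pattern, 1L, 1L)
  s2 <- substr(pattern, 2L, 2L)
  unname(paste0(.iupac_complement[s2], .iupac_complement[s1]))
}

#' Group dinucleotide patterns with their reverse complements
#'
#' Partitions the 100 degenerate dinucleotides into equivalence classes under
#' reverse complementation: palindromic patterns (equal to their own reverse
#' complement) form singleton sets and the rest pair up, giving 10 palindromic
#' and 45 complementary-pair sets (55 in total).  Spacings of the members of a
#' set are pooled when the set is profiled, since a motif and its complement
#' show the same periodicity on the two strands.
#'
#' @param patterns Patterns to group; defaults to all 100.
#' @return A data frame with one row per set: `set` (label), `member1`,
#'   `member2` (`NA` for palindromes) and `palindromic`.
#' @examples
#' sets <- motif_sets()
#' nrow(sets)                 # 55
#' sum(sets$palindromic)      # 10
#' @export
motif_sets <- function(patterns = dinucleotide_patterns()) {
  rc <- pattern_revcomp(patterns)
  seen <- character(0)
  rows <- vector("list", length(patterns))
  k <- 0L
  for (i in seq_along(patterns)) {
    p <- patterns[i]
    if (p %in% seen) next
    q <- rc[i]
    k <- k + 1L
    if (p == q) {
      rows[[k]] <- data.frame(set = p, member1 = p, member2 = NA_character_,
                              palindromic = TRUE, stringsAsFactors = FALSE)
      seen <- c(seen, p)
    } else {
      rows[[k]] <- data.frame(set = paste0(p, "/", q), member1 = p,
                              member2 = q, palindromic = FALSE,
                              stringsAsFactors = FALSE)
      seen <- c(seen, p, q)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

# dinucleotide codes (1..16) matched by a degenerate pattern
pattern_match_codes <- function(pattern) {
  .check_pattern(pattern)
  b1 <- .iupac_match[[substr(pattern, 1L, 1L)]]
  b2 <- .iupac_match[[substr(pattern, 2L, 2L)]]
  as.integer(outer(b1, b2, function(x, y) (x - 1L) * 4L + y))
}

# weight vector w (length 256) with w[a + 16*(b-1)] = number of patterns whose
# match set contains both dinucleotide codes a and b; spacing counts of the
# pooled pattern collection are then crossprod(pair_count_table, w)
pattern_weight_vector <- function(patterns) {
  w <- numeric(256L)
  for (p in patterns) {
    m <- pattern_match_codes(p)
    idx <- as.integer(outer(m, m, function(a, b) a + 16L * (b - 1L)))
    w[idx] <- w[idx] + 1
  }
  w
}
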