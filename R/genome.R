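# Genome containers, FASTA / gene-model input, replicore splitting.

#' Create a genome record
#'
#' Lightweight container for a single replicon: the sequence, an identifier,
#' optional replication origin / terminus coordinates (1-based), and an
#' optional gene-model table used for codon-position filtering and the
#' codon-structure-preserving shuffler.
#'
#' @param sequence Single character string of bases (IUPAC letters allowed;
#'   ambiguous bases never match any pattern).
#' @param id Replicon identifier.
#' @param origin,terminus Optional 1-based coordinates of the replication
#'   origin and terminus (dif site), required for replicore analyses.
#' @param genes Optional data frame with columns `start`, `end`, `strand`
#'   (`"+"`/`"-"`) and `frame` (0, 1 or 2), 1-based closed intervals.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(sequence, id = "genome", origin = NULL,
                          terminus = NULL, genes = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  for (coord in list(origin, terminus))
    if (!is.null(coord) && (coord < 1L || coord > L))
      stop("origin/terminus outside the sequence", call. = FALSE)
  if (!is.null(genes)) {
    genes <- as.data.frame(genes)
    need <- c("start", "end", "strand", "frame")
    if (!all(need %in% names(genes)))
      stop("genes must have columns start, end, strand, frame", call. = FALSE)
    if (any(genes$start < 1L) || any(genes$end > L) ||
        any(genes$end < genes$start))
      stop("gene coordinates outside the sequence", call. = FALSE)
  }
  structure(list(sequence = sequence, id = id, length = L,
                 origin = origin, terminus = terminus, genes = genes),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$id, ": ", format(x$length, big.mark = ","),
      " bp", sep = "")
  if (!is.null(x$origin)) cat("; ori", x$origin, "/ ter", x$terminus)
  if (!is.null(x$genes)) cat(";", nrow(x$genes), "gene models")
  cat("\n")
  invisible(x)
}

#' Read a genome from FASTA
#'
#' Reads a (possibly gzipped) FASTA file.  When the file holds several
#' records, the largest replicon is kept by default, since chromosome-level
#' periodicity is measured on the main replicon.
#'
#' @param file Path to a FASTA file (plain or gzip).
#' @param largest_only Keep only the largest record (default) or error when
#'   several records are present and this is `FALSE`.
#' @param origin,terminus,genes Passed to [genome_record()]; `genes` may also
#'   be a file path understood by [read_gene_models()].
#' @return A [genome_record()].
#' @export
read_genome <- function(file, largest_only = TRUE, origin = NULL,
                        terminus = NULL, genes = NULL) {
  dss <- Biostrings::readDNAStringSet(file)
  if (length(dss) == 0L) stop("no sequences in ", file, call. = FALSE)
  i <- 1L
  if (length(dss) > 1L) {
    if (!largest_only)
      stop("multiple records in ", file,
           "; set largest_only = TRUE to keep the largest replicon",
           call. = FALSE)
    i <- which.max(Biostrings::width(dss))
  }
  if (is.character(genes)) genes <- read_gene_models(genes)
  genome_record(as.character(dss[[i]]),
                id = sub("\\s.*$", "", names(dss)[i]),
                origin = origin, terminus = terminus, genes = genes)
}

#' Read gene models from GFF3 or a simple table
#'
#' GFF3 files (`.gff`/`.gff3`, CDS features; frame taken from the phase
#' column) are parsed with \pkg{rtracklayer}; anything else is read as a
#' tab-separated table with columns seqid, start, end, strand, frame.
#'
#' @param file Path to a GFF3 or 5-column TSV file.
#' @return Data frame with columns `start`, `end`, `strand`, `frame`.
#' @export
read_gene_models <- function(file) {
  if (grepl("\\.gff3?(\\.gz)?$", file, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    gr <- as.data.frame(rtracklayer::import(file))
    gr <- gr[gr$type == "CDS", , drop = FALSE]
    ph <- if ("phase" %in% names(gr)) as.integer(gr$phase) else
      rep(0L, nrow(gr))
    ph[is.na(ph)] <- 0L
    data.frame(start = gr$start, end = gr$end,
               strand = as.character(gr$strand),
               frame = ph, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(file, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 5L)
      stop("gene table needs 5 columns: seqid, start, end, strand, frame",
           call. = FALSE)
    data.frame(start = as.integer(tab[[2L]]), end = as.integer(tab[[3L]]),
               strand = as.character(tab[[4L]]), frame = as.integer(tab[[5L]]),
               stringsAsFactors = FALSE)
  }
}

#' Split a chromosome into its two replicores
#'
#' Returns the two chromosome arms between the replication origin and the
#' terminus.  The circular chromosome wraps at the end of the linear string,
#' so each arc is contiguous; spacings never span the origin or terminus when
#' histograms are built per replicore.
#'
#' @param g A [genome_record()] with `origin` and `terminus` set.
#' @return List with elements `right` (origin to terminus) and `left`
#'   (terminus back to origin), both `genome_record`s.
#' @export
split_replicores <- function(g) {
  stopifnot(inherits(g, "genome_record"))
  if (is.null(g$origin) || is.null(g$terminus))
    stop("origin/terminus not set; analyze the whole replicon instead",
         call. = FALSE)
  arc <- function(from, to) {  # [from, to) walking rightwards with wrap
    if (from < to) substr(g$sequence, from, to - 1L)
    else paste0(substr(g$sequence, from, g$length),
                substr(g$sequence, 1L, to - 1L))
  }
  list(right = genome_record(arc(g$origin, g$terminus),
                             id = paste0(g$id, "_right")),
       left = genome_record(arc(g$terminus, g$origin),
                            id = paste0(g$id, "_left")))
}

#' Reverse complement of a sequence or genome record
#'
#' @param x A `genome_record` or a sequence string.
#' @return The reverse-complemented sequence as a character string.
#' @export
revcomp_sequence <- function(x) {
  s <- as_sequence(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
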