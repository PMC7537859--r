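# Small internal helpers.

# run expr under a temporary RNG seed, restoring the caller's RNG state;
# seed = NULL means "use the global RNG stream as-is"
with_seed <- function(seed, expr) {
  expr <- substitute(expr)
  if (is.null(seed)) return(eval(expr, parent.frame()))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  eval(expr, parent.frame())
}

# encode a base string as integer codes A=1, C=2, G=3, T=4, NA for anything else
encode_bases <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]],
        c("A", "C", "G", "T"))
}

# dinucleotide code (1..16) at each start position; 0 where ambiguous
dinuc_codes <- function(base_codes) {
  n <- length(base_codes)
  if (n < 2L) return(integer(0))
  d <- (base_codes[-n] - 1L) * 4L + base_codes[-1L]
  d[is.na(d)] <- 0L
  as.integer(d)
}

decode_bases <- function(codes) {
  paste(c("A", "C", "G", "T")[codes], collapse = "")
}

as_sequence <- function(x) {
  if (inherits(x, "genome_record")) return(x$sequence)
  if (is.character(x) && length(x) == 1L) return(x)
  stop("expected a genome_record or a single sequence string", call. = FALSE)
}
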