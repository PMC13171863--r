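# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Overwrite genome sequence `seq` with `motif` at 0-based position `start`.
plant_motif <- function(seq, start, motif) {
  stopifnot(start >= 0, start + nchar(motif) <= nchar(seq))
  paste0(substr(seq, 1L, start), motif,
         substr(seq, start + nchar(motif) + 1L, nchar(seq)))
}

# Extract [start, end) 0-based half-open from a sequence string.
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# round() uses banker's rounding; printed percentages/Mbp use half-up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

variant_key <- function(records) {
  paste(records$contig, records$pos, records$ref, records$alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
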