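# Shared fixtures, built once per test run.

MODELS <- default_splice_models()
REF <- make_reference(seed = 1)
GSET <- simulate_pedigree_vcf(REF, n_background = 200, seed = 7)

causal_key <- function(ref) {
  with(ref$truth$causal, paste(contig, pos, ref, alt, sep = ":"))
}

variant_keys_of <- function(records) {
  paste(records$contig, records$pos, records$ref, records$alt, sep = ":")
}

# A minimal genotype set for hand-built ROH scenarios.
toy_gset <- function(pos, gt, contig = "chrT", individual = "I1") {
  geno <- matrix(as.integer(gt), ncol = 1,
                 dimnames = list(NULL, individual))
  list(variants = data.frame(contig = contig, pos = as.integer(pos),
                             ref = "A", alt = "C",
                             stringsAsFactors = FALSE),
       geno = geno)
}

# Independent per-base membership oracle for interval intersection.
per_base_shared <- function(segments, universe_end) {
  ids <- unique(segments$individual)
  covered <- vapply(ids, function(id) {
    s <- segments[segments$individual == id, ]
    base <- rep(FALSE, universe_end)
    for (i in seq_len(nrow(s))) {
      if (s$end[i] > s$start[i]) base[(s$start[i] + 1):s$end[i]] <- TRUE
    }
    base
  }, logical(universe_end))
  rowSums(covered) == length(ids)
}

# Maximal TRUE runs of a logical vector as 0-based half-open intervals.
runs_from_mask <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}
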