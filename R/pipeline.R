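#' End-to-end deep-intronic variant discovery
#'
#' Runs the full inference chain on a simulated (or real, suitably shaped)
#' pedigree variant set: genome-wide-mode filters (population frequency,
#' allele fraction, gene locus, recessive segregation), per-affected
#' run-of-homozygosity detection, shared homozygosity-by-descent
#' intersection, restriction of candidates to shared regions, ref/alt
#' splice-site scanning of each surviving variant, and pseudoexon partner
#' search for every activated site. Candidates from all variants are pooled
#' and ranked by combined splice-site score.
#'
#' @param gset a `variant_set` (with `pedigree`).
#' @param gene_model a `gene_model`.
#' @param genome named character vector of contig sequences.
#' @param models splice models (default [default_splice_models()]).
#' @param maf_max,vaf_min frequency and allele-fraction thresholds
#'   (genome-wide-mode defaults 0.005 and 0.2).
#' @param roh_min_length,roh_max_het,roh_min_markers run-scan parameters
#'   (synthetic-scale defaults; use 1e6/1/25 at human scale).
#' @param hbd_min_length minimum shared-region length.
#' @param activation_threshold donor/acceptor activation score.
#' @param partner_min_score,search_window,min_len,max_len partner-search
#'   parameters (see [find_partners()]).
#' @return list: `filtered` (surviving variant records), `roh` (per-affected
#'   runs), `hbd` (shared regions), `candidates` (pooled ranked candidate
#'   table), `top` (best candidate row or NULL).
#' @export
run_discovery_pipeline <- function(gset, gene_model, genome,
                                   models = default_splice_models(),
                                   maf_max = 0.005, vaf_min = 0.2,
                                   roh_min_length = 50000L,
                                   roh_max_het = 1L, roh_min_markers = 10L,
                                   hbd_min_length = 50000L,
                                   activation_threshold = 10,
                                   partner_min_score = 4,
                                   search_window = 500L,
                                   min_len = 25L, max_len = 500L) {
  rec <- filter_frequency(gset$variants, maf_max, "keep")
  rec <- filter_vaf(rec, vaf_min)
  rec <- filter_region(rec, gene_model, "locus")
  keys <- variant_key(gset$variants)
  geno <- gset$geno[match(variant_key(rec), keys), , drop = FALSE]
  rec <- segregation_filter(rec, geno, gset$pedigree)

  affected <- gset$pedigree$id[gset$pedigree$affected]
  roh <- do.call(rbind, lapply(affected, function(id) {
    detect_roh(gset, id, min_length = roh_min_length,
               max_het = roh_max_het, min_markers = roh_min_markers)
  }))
  hbd <- if (is.null(roh) || nrow(roh) == 0L) {
    data.frame(contig = character(), start = integer(), end = integer(),
               size_mbp = numeric(), members = character())
  } else {
    intersect_hbd(roh, min_length = hbd_min_length)
  }

  if (nrow(hbd) > 0L && nrow(rec) > 0L) {
    in_hbd <- vapply(seq_len(nrow(rec)), function(i) {
      any(hbd$contig == rec$contig[i] & hbd$start < rec$pos[i] &
            rec$pos[i] <= hbd$end)
    }, logical(1))
    rec <- rec[in_hbd, , drop = FALSE]
  }

  cands <- list()
  for (i in seq_len(nrow(rec))) {
    deltas <- scan_variant(models, genome, rec[i, , drop = FALSE],
                           strand = gene_model$strand)
    act <- deltas[deltas$alt_score >= activation_threshold &
                    deltas$delta > 0, , drop = FALSE]
    for (j in seq_len(nrow(act))) {
      cand <- find_partners(act[j, , drop = FALSE], genome, models,
                            search_window = search_window,
                            partner_min_score = partner_min_score,
                            min_len = min_len, max_len = max_len,
                            activation_threshold = activation_threshold)
      if (nrow(cand) > 0L) cands[[length(cands) + 1L]] <- cand
    }
  }
  candidates <- if (length(cands) > 0L) {
    pooled <- do.call(rbind, cands)
    pooled <- pooled[order(-pooled$combined_score), , drop = FALSE]
    pooled$rank <- seq_len(nrow(pooled))
    rownames(pooled) <- NULL
    pooled
  } else {
    NULL
  }
  list(filtered = rec, roh = roh, hbd = hbd, candidates = candidates,
       top = if (!is.null(candidates)) candidates[1, , drop = FALSE])
}

#' Reciprocal overlap of two intervals
#'
#' Overlap length divided by the longer of the two interval lengths is a
#' stricter criterion than either one-sided fraction; this returns the
#' minimum of the two one-sided fractions (0 when disjoint).
#'
#' @param a_start,a_end,b_start,b_end interval boundaries (half-open).
#' @return numeric in \[0, 1\].
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  ov <- max(0, min(a_end, b_end) - max(a_start, b_start))
  if (ov == 0) return(0)
  min(ov / (a_end - a_start), ov / (b_end - b_start))
}
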