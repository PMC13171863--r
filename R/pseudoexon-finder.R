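#' Delineate candidate pseudoexons around an activated splice site
#'
#' Given a variant-activated splice site (a row of [scan_variant()] output
#' whose alternate-allele score reaches the activation threshold), scans the
#' reference sequence for partner sites: for an activated donor, acceptor
#' windows upstream; for an activated acceptor, donor windows downstream.
#' Each partner passing `partner_min_score` defines a candidate pseudoexon
#' running from the first exonic base after the acceptor AG to the last
#' exonic base before the donor GT, so candidate length equals the
#' acceptor-to-donor boundary distance.
#'
#' @param delta one row of [scan_variant()] output (the activated site).
#' @param genome named character vector of contig sequences.
#' @param models list with `donor` and `acceptor` `splice_model`s.
#' @param search_window maximum scan distance from the activated site in bp.
#' @param partner_min_score minimum partner log2 score.
#' @param min_len,max_len candidate length bounds in nt.
#' @param activation_threshold required alternate-allele score of `delta`.
#' @return data.frame of class `pseudoexon_candidates`: `contig`,
#'   `acceptor_pos`, `donor_pos` (0-based boundaries), `length`,
#'   `acceptor_score`, `donor_score`, `combined_score`, `variant`, `rank`.
#' @export
find_partners <- function(delta, genome, models, search_window = 500L,
                          partner_min_score = 4, min_len = 25L,
                          max_len = 500L, activation_threshold = 10) {
  stopifnot(nrow(delta) == 1L)
  if (delta$alt_score < activation_threshold) {
    stop("activated site score below activation threshold")
  }
  seq <- genome[[delta$contig]]
  reach <- min(search_window, max_len)
  empty <- data.frame(contig = character(), acceptor_pos = integer(),
                      donor_pos = integer(), length = integer(),
                      acceptor_score = numeric(), donor_score = numeric(),
                      combined_score = numeric(), variant = character(),
                      rank = integer(), stringsAsFactors = FALSE)

  if (delta$kind == "donor") {
    d <- delta$boundary
    lo <- d - reach
    if (lo - 20L < 0L) {
      warning("search window truncated at contig start")
      lo <- 20L
    }
    if (d - min_len < max(lo, 20L)) return(empty)
    acc_bounds <- seq.int(max(lo, 20L), d - min_len)
    acc_bounds <- acc_bounds[d - acc_bounds >= min_len & d - acc_bounds <= max_len]
    if (length(acc_bounds) == 0L) return(empty)
    scores <- vapply(acc_bounds, function(a) {
      score_site(models$acceptor, subseq0(seq, a - 20L, a + 3L))
    }, numeric(1))
    keep <- !is.na(scores) & scores >= partner_min_score
    if (!any(keep)) return(empty)
    res <- data.frame(contig = delta$contig,
                      acceptor_pos = acc_bounds[keep], donor_pos = d,
                      length = d - acc_bounds[keep],
                      acceptor_score = scores[keep],
                      donor_score = delta$alt_score,
                      variant = delta$variant,
                      stringsAsFactors = FALSE)
  } else {
    a <- delta$boundary
    hi <- a + reach
    if (hi + 6L > nchar(seq)) {
      warning("search window truncated at contig end")
      hi <- nchar(seq) - 6L
    }
    if (hi < a + min_len) return(empty)
    don_bounds <- seq.int(a + min_len, hi)
    don_bounds <- don_bounds[don_bounds - a >= min_len & don_bounds - a <= max_len]
    if (length(don_bounds) == 0L) return(empty)
    scores <- vapply(don_bounds, function(d) {
      score_site(models$donor, subseq0(seq, d - 3L, d + 6L))
    }, numeric(1))
    keep <- !is.na(scores) & scores >= partner_min_score
    if (!any(keep)) return(empty)
    res <- data.frame(contig = delta$contig,
                      acceptor_pos = a, donor_pos = don_bounds[keep],
                      length = don_bounds[keep] - a,
                      acceptor_score = delta$alt_score,
                      donor_score = scores[keep],
                      variant = delta$variant,
                      stringsAsFactors = FALSE)
  }
  if (nrow(res) == 0L) return(empty)
  res$combined_score <- res$acceptor_score + res$donor_score
  res <- res[order(-res$combined_score), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res <- res[, c("contig", "acceptor_pos", "donor_pos", "length",
                 "acceptor_score", "donor_score", "combined_score",
                 "variant", "rank")]
  rownames(res) <- NULL
  class(res) <- c("pseudoexon_candidates", class(res))
  res
}

#' Flag candidates matching annotated exons
#'
#' A candidate whose acceptor and donor boundaries both match a known exon
#' of the gene model within `slop` bp is flagged: such a "pseudoexon" is in
#' fact an annotated exon.
#'
#' @param candidates output of [find_partners()].
#' @param gene_model a `gene_model` with a `known_exons` table.
#' @param slop boundary tolerance in bp (default 0).
#' @return `candidates` with an added logical `annotated_exon` column.
#' @export
annotate_known_exons <- function(candidates, gene_model, slop = 0L) {
  ke <- gene_model$known_exons
  candidates$annotated_exon <- vapply(seq_len(nrow(candidates)), function(i) {
    any(abs(ke$start - candidates$acceptor_pos[i]) <= slop &
          abs(ke$end - candidates$donor_pos[i]) <= slop)
  }, logical(1))
  candidates
}
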