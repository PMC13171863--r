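#' Percent spliced in from junction counts
#'
#' `psi = inclusion / (inclusion + 2 * exclusion)`, where inclusion is the
#' summed read count of the two flanking inclusion junctions and exclusion
#' the count of the skipping junction; the factor 2 balances the exclusion
#' junction against the two inclusion junctions each inclusion molecule
#' spans. A zero denominator (no coverage) yields `NA`, not 0.
#'
#' @param inclusion,exclusion non-negative junction read counts
#'   (vectorized).
#' @return numeric PSI in \[0, 1\], `NA` where the denominator is 0.
#' @export
compute_psi <- function(inclusion, exclusion) {
  if (any(inclusion < 0 | exclusion < 0, na.rm = TRUE)) {
    stop("junction counts must be non-negative")
  }
  denom <- inclusion + 2 * exclusion
  ifelse(denom > 0, inclusion / denom, NA_real_)
}

#' PSI estimate for a pseudoexon from a junction-count table
#'
#' Looks up the two inclusion junctions (5' flank to pseudoexon, pseudoexon
#' to 3' flank) and the exclusion junction (flank to flank) in a
#' STAR-dialect junction table (1-based first/last intronic base) and
#' applies [compute_psi()]. A junction absent from the table counts 0; if
#' all three are absent the estimate is `NA` with a warning.
#'
#' @param counts junction data.frame (`contig`, `intron_start`,
#'   `intron_end`, `strand`, `unique_count`).
#' @param pseudoexon list or one-row data.frame with `acceptor_pos`,
#'   `donor_pos` (0-based boundaries).
#' @param flank5,flank3 one-row data.frames with `start`, `end` (0-based
#'   half-open) for the canonical exons flanking the host intron.
#' @return list of class `psi_estimate`: `inclusion`, `exclusion`, `psi`.
#' @export
junctions_to_psi <- function(counts, pseudoexon, flank5, flank3) {
  if (pseudoexon$acceptor_pos < flank5$end ||
      pseudoexon$donor_pos > flank3$start) {
    stop("pseudoexon must lie between the flanking exons")
  }
  lookup <- function(intron_start, intron_end) {
    hit <- counts$intron_start == intron_start &
      counts$intron_end == intron_end
    if (!any(hit)) return(NA_integer_)
    sum(counts$unique_count[hit])
  }
  inc1 <- lookup(flank5$end + 1L, pseudoexon$acceptor_pos)
  inc2 <- lookup(pseudoexon$donor_pos + 1L, flank3$start)
  excl <- lookup(flank5$end + 1L, flank3$start)
  if (all(is.na(c(inc1, inc2, excl)))) {
    warning("no supporting junctions found for pseudoexon")
    return(structure(list(inclusion = NA_integer_, exclusion = NA_integer_,
                          psi = NA_real_), class = "psi_estimate"))
  }
  inclusion <- sum(inc1, inc2, na.rm = TRUE)
  exclusion <- if (is.na(excl)) 0L else excl
  structure(list(inclusion = inclusion, exclusion = exclusion,
                 psi = compute_psi(inclusion, exclusion)),
            class = "psi_estimate")
}

#' PSI for a named planted pseudoexon of a gene model
#'
#' Convenience wrapper around [junctions_to_psi()] using the gene model's
#' pseudoexon table and its last two exons as flanks.
#'
#' @param counts junction data.frame.
#' @param gene_model a `gene_model`.
#' @param pe pseudoexon name, e.g. `"PE3"`.
#' @return a `psi_estimate`.
#' @export
psi_for_pe <- function(counts, gene_model, pe = "PE3") {
  pes <- gene_model$pseudoexons
  row <- pes[pes$pe == pe, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown pseudoexon: ", pe)
  n_ex <- nrow(gene_model$exons)
  junctions_to_psi(counts, row,
                   gene_model$exons[n_ex - 1L, ],
                   gene_model$exons[n_ex, ])
}
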