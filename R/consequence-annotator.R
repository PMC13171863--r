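#' Build a transcript isoform with inserted pseudoexons
#'
#' Splices the canonical exons of a gene model together with zero or more
#' pseudoexons (each within one intron) in genomic order, producing the
#' spliced sequence and the exon-junction positions in transcript
#' coordinates.
#'
#' @param genome named character vector of contig sequences.
#' @param gene_model a `gene_model`.
#' @param pseudoexons `NULL` (canonical transcript) or a data.frame with
#'   `start`, `end` (0-based half-open genomic intervals), e.g. built from
#'   `acceptor_pos`/`donor_pos` of [find_partners()] candidates.
#' @param label isoform label (default composed from the input).
#' @return list of class `transcript_isoform`: `label`, `segments`
#'   (data.frame `start`, `end`, `kind`), `seq`, `junctions` (0-based
#'   transcript positions of exon-exon junctions: position of the first
#'   base after each junction).
#' @export
build_isoform <- function(genome, gene_model, pseudoexons = NULL,
                          label = NULL) {
  ex <- gene_model$exons
  segs <- data.frame(start = ex$start, end = ex$end, kind = "exon",
                     stringsAsFactors = FALSE)
  if (!is.null(pseudoexons) && nrow(pseudoexons) > 0L) {
    pe <- data.frame(start = pseudoexons$start, end = pseudoexons$end,
                     kind = "pseudoexon", stringsAsFactors = FALSE)
    intronic <- vapply(seq_len(nrow(pe)), function(i) {
      any(ex$end[-nrow(ex)] <= pe$start[i] & pe$end[i] <= ex$start[-1])
    }, logical(1))
    if (!all(intronic)) stop("each pseudoexon must lie within one intron")
    segs <- rbind(segs, pe)
  }
  segs <- segs[order(segs$start), , drop = FALSE]
  if (any(segs$start[-1] < segs$end[-nrow(segs)])) {
    stop("overlapping segments in isoform")
  }
  rownames(segs) <- NULL
  seq <- paste(vapply(seq_len(nrow(segs)), function(i) {
    subseq0(genome[[gene_model$contig]], segs$start[i], segs$end[i])
  }, character(1)), collapse = "")
  if (gene_model$strand == "-") seq <- revcomp(seq)
  lens <- segs$end - segs$start
  junctions <- cumsum(lens)[-length(lens)]
  structure(list(label = label %||% paste(c("iso", segs$kind), collapse = "."),
                 segments = segs, seq = seq, junctions = junctions,
                 gene = gene_model$gene, strand = gene_model$strand),
            class = "transcript_isoform")
}

# 0-based transcript coordinate of a 0-based genomic position (+ strand).
tx_coord <- function(isoform, gpos) {
  segs <- isoform$segments
  offs <- cumsum(c(0L, segs$end - segs$start))
  i <- which(segs$start <= gpos & gpos < segs$end)
  if (length(i) == 0L) {
    # boundary position: end of the last segment before it
    i <- max(which(segs$end <= gpos))
    return(offs[i + 1L])
  }
  offs[i] + (gpos - segs$start[i])
}

#' Annotate the protein-level consequence of an isoform
#'
#' Translates the isoform from the canonical start codon and reports:
#' reading-frame status (an inserted length not divisible by 3 shifts the
#' frame), the last canonical residue retained before the first insertion,
#' the number of novel amino acids translated before the first stop, and
#' whether that stop is premature (upstream of the canonical termination
#' codon's position in this isoform).
#'
#' @param isoform a `transcript_isoform` built on `gene_model`.
#' @param gene_model the `gene_model` carrying the CDS definition.
#' @return list of class `consequence_report`: `frame_status` (`"in-frame"`
#'   or `"frameshift"`), `inserted_len`, `last_canonical_aa`, `novel_aa`,
#'   `ptc_present`, `ptc_tx_pos` (0-based transcript position of the stop
#'   codon, NA if none), `protein` (translated sequence to the stop).
#' @export
annotate_consequence <- function(isoform, gene_model) {
  segs <- isoform$segments
  if (isoform$strand != "+") {
    stop("consequence annotation implemented for + strand gene models")
  }
  cds_tx <- tx_coord(isoform, gene_model$cds_start)
  if (subseq0(isoform$seq, cds_tx, cds_tx + 3L) != "ATG") {
    stop("CDS does not begin with a start codon")
  }
  ins <- segs[segs$kind == "pseudoexon", , drop = FALSE]
  inserted_len <- sum(ins$end - ins$start)
  frame_status <- if (inserted_len %% 3L == 0L) "in-frame" else "frameshift"

  coding <- subseq0(isoform$seq, cds_tx, nchar(isoform$seq))
  n_codon <- nchar(coding) %/% 3L
  codons <- substring(coding, 3L * (seq_len(n_codon) - 1L) + 1L,
                      3L * seq_len(n_codon))
  stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))[1]
  aa <- Biostrings::translate(
    Biostrings::DNAString(substr(coding, 1L, 3L * n_codon)),
    if.fuzzy.codon = "X")
  aa <- as.character(aa)
  protein <- if (is.na(stop_idx)) aa else substr(aa, 1L, stop_idx - 1L)

  if (nrow(ins) > 0L) {
    ins_tx <- tx_coord(isoform, min(ins$start))
    upstream <- ins_tx - cds_tx
    last_canonical_aa <- upstream %/% 3L
  } else {
    last_canonical_aa <- nchar(protein)
  }
  novel_aa <- max(0L, nchar(protein) - last_canonical_aa)

  canonical_stop_tx <- tx_coord(isoform, gene_model$cds_end - 3L)
  ptc_tx_pos <- if (is.na(stop_idx)) NA_integer_ else
    cds_tx + 3L * (stop_idx - 1L)
  ptc_present <- !is.na(ptc_tx_pos) && ptc_tx_pos < canonical_stop_tx

  structure(list(frame_status = frame_status, inserted_len = inserted_len,
                 last_canonical_aa = last_canonical_aa, novel_aa = novel_aa,
                 ptc_present = ptc_present, ptc_tx_pos = ptc_tx_pos,
                 protein = protein),
            class = "consequence_report")
}

#' Predict nonsense-mediated decay
#'
#' Applies the 50-nt rule: a transcript is predicted to be degraded by NMD
#' when its premature termination codon lies at least `rule_threshold` nt
#' upstream of the final exon-exon junction. A PTC in the last exon escapes.
#' In a reporter (minigene) context without a genuine open reading frame,
#' NMD prediction is not applicable and `NA` is returned.
#'
#' @param report a `consequence_report`.
#' @param isoform the `transcript_isoform` the report was computed on.
#' @param rule_threshold distance rule in nt (default 50).
#' @param no_orf reporter context flag: `TRUE` returns `NA`.
#' @return logical NMD prediction (or `NA`).
#' @export
predict_nmd <- function(report, isoform, rule_threshold = 50L,
                        no_orf = FALSE) {
  if (no_orf) return(NA)
  if (!isTRUE(report$ptc_present)) return(FALSE)
  final_junction <- max(isoform$junctions)
  (final_junction - report$ptc_tx_pos) >= rule_threshold
}

#' Report protein domains lost to truncation
#'
#' Lists domains wholly or partly lost given the last canonical residue
#' retained in a truncated product.
#'
#' @param report a `consequence_report`.
#' @param domain_map named list of `c(start, end)` residue ranges
#'   (1-based inclusive).
#' @param protein_length canonical protein length in residues.
#' @return data.frame: `domain`, `start`, `end`, `status`
#'   (`"retained"`, `"partly-lost"`, `"lost"`).
#' @export
domain_impact <- function(report, domain_map, protein_length) {
  last <- report$last_canonical_aa
  stopifnot(all(vapply(domain_map, function(d) d[2] <= protein_length,
                       logical(1))))
  status <- vapply(domain_map, function(d) {
    if (last >= d[2]) "retained"
    else if (last >= d[1]) "partly-lost"
    else "lost"
  }, character(1))
  data.frame(domain = names(domain_map),
             start = vapply(domain_map, `[`, numeric(1), 1),
             end = vapply(domain_map, `[`, numeric(1), 2),
             status = status, row.names = NULL, stringsAsFactors = FALSE)
}
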