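#' Variant filters
#'
#' All filters are pure, order-preserving subset operations over a variant
#' record data.frame (columns `contig`, `pos` 1-based, `ref`, `alt`, plus
#' `maf` and `vaf` where relevant), so they are idempotent and compose in
#' any order with intersection semantics.
#'
#' @name variant_filters
NULL

#' Population-frequency filter
#'
#' Keeps records with minor allele frequency strictly below `maf_max`
#' (the strict inequality mirrors the usual "MAF < x" filter wording).
#' Records with no MAF annotation are kept by default: a variant absent
#' from a frequency database is rare by implication.
#'
#' @param records variant data.frame with a `maf` column (NA = unannotated).
#' @param maf_max frequency threshold in (0, 0.5].
#' @param missing_policy `"keep"` or `"drop"` records with missing MAF.
#' @return the surviving subset, input order preserved.
#' @export
filter_frequency <- function(records, maf_max,
                             missing_policy = c("keep", "drop")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(maf_max > 0, maf_max <= 0.5)
  keep <- records$maf < maf_max
  keep[is.na(keep)] <- missing_policy == "keep"
  records[keep, , drop = FALSE]
}

#' Variant-allele-fraction filter
#'
#' Keeps records whose sample variant allele fraction is strictly greater
#' than `vaf_min`. Records without a VAF annotation are kept (cannot be
#' assessed); set `missing_policy = "drop"` to remove them.
#'
#' @param records variant data.frame with a `vaf` column.
#' @param vaf_min threshold in \[0, 1\].
#' @param missing_policy `"keep"` or `"drop"` records with missing VAF.
#' @return the surviving subset.
#' @export
filter_vaf <- function(records, vaf_min, missing_policy = c("keep", "drop")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(vaf_min >= 0, vaf_min <= 1)
  keep <- records$vaf > vaf_min
  keep[is.na(keep)] <- missing_policy == "keep"
  records[keep, , drop = FALSE]
}

#' Region filter
#'
#' `mode = "panel"` keeps records within any coding exon extended by `pad`
#' intronic bases on each side (the targeted-panel filter); `mode = "locus"`
#' keeps records anywhere within the gene span, coding or non-coding (the
#' genome-wide locus filter that can reach deep-intronic variants). Records
#' on contigs not covered by the gene model are excluded and counted in the
#' `n_offcontig` attribute of the result.
#'
#' @param records variant data.frame.
#' @param gene_model a `gene_model` (see [make_reference()]).
#' @param mode `"panel"` or `"locus"`.
#' @param pad intronic padding in bp for panel mode (default 20).
#' @return surviving subset, with attribute `n_offcontig`.
#' @export
filter_region <- function(records, gene_model, mode = c("panel", "locus"),
                          pad = 20L) {
  mode <- match.arg(mode)
  stopifnot(pad >= 0)
  on_contig <- records$contig == gene_model$contig
  pos0 <- records$pos - 1L
  if (mode == "panel") {
    cex <- coding_exons(gene_model)
    win <- IRanges::IRanges(start = cex$start - pad + 1L, end = cex$end + pad)
    hit <- IRanges::overlapsAny(IRanges::IRanges(pos0 + 1L, pos0 + 1L), win)
  } else {
    span_start <- min(gene_model$exons$start)
    span_end <- max(gene_model$exons$end)
    hit <- pos0 >= span_start & pos0 < span_end
  }
  keep <- on_contig & hit
  out <- records[keep, , drop = FALSE]
  attr(out, "n_offcontig") <- sum(!on_contig)
  out
}

# Intersection of exons with the CDS interval, 0-based half-open.
coding_exons <- function(gene_model) {
  ex <- gene_model$exons
  s <- pmax(ex$start, gene_model$cds_start)
  e <- pmin(ex$end, gene_model$cds_end)
  ok <- s < e
  data.frame(start = s[ok], end = e[ok])
}

#' Recessive segregation filter
#'
#' Keeps sites that are homozygous for the alternate allele in every
#' genotyped affected individual and heterozygous in every genotyped parent
#' of an affected individual — the homozygous-by-descent configuration
#' expected for a recessive variant in a consanguineous pedigree.
#'
#' @param records variant data.frame.
#' @param genotypes integer matrix (sites x individuals; 0 = hom-ref,
#'   1 = het, 2 = hom-alt, NA = missing), rows aligned with `records`.
#' @param pedigree data.frame with columns `id`, `affected` (logical),
#'   `father`, `mother` (NA allowed).
#' @param model currently only `"recessive-hom"`.
#' @param missing_policy `"drop"` removes a site when any required call is
#'   missing (conservative default); `"ignore"` skips the uncalled
#'   individual instead.
#' @return surviving subset.
#' @export
segregation_filter <- function(records, genotypes, pedigree,
                               model = "recessive-hom",
                               missing_policy = c("drop", "ignore")) {
  model <- match.arg(model)
  missing_policy <- match.arg(missing_policy)
  stopifnot(nrow(genotypes) == nrow(records))
  affected <- pedigree$id[pedigree$affected]
  affected <- intersect(affected, colnames(genotypes))
  if (length(affected) == 0L) {
    stop("no genotyped affected individuals in pedigree")
  }
  parents <- unique(stats::na.omit(c(
    pedigree$father[pedigree$affected], pedigree$mother[pedigree$affected])))
  parents <- intersect(parents, colnames(genotypes))

  ga <- genotypes[, affected, drop = FALSE]
  gp <- genotypes[, parents, drop = FALSE]
  if (missing_policy == "drop") {
    ok <- rowSums(ga == 2L) == length(affected)
    if (length(parents) > 0L) ok <- ok & rowSums(gp == 1L) == length(parents)
    ok[is.na(ok)] <- FALSE
  } else {
    ok <- apply(ga, 1L, function(g) all(g == 2L, na.rm = TRUE))
    if (length(parents) > 0L) {
      ok <- ok & apply(gp, 1L, function(g) all(g == 1L, na.rm = TRUE))
    }
  }
  records[ok, , drop = FALSE]
}
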