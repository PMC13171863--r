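#' File input/output
#'
#' Writers emit the field's standard plain-text formats (FASTA, VCF 4.2,
#' 6-column gene-model TSV, STAR-dialect junction TSV); readers round-trip
#' them. VCF parsing is delegated to vcfR.
#'
#' @name pexscan_io
NULL

#' Write a genome as FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read a FASTA genome
#'
#' @param path FASTA file.
#' @return named character vector of uppercase contig sequences.
#' @export
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(dna))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a gene model as 6-column TSV
#'
#' Columns: gene, contig, strand, feature, start, end (0-based half-open).
#' Features: `exon`, `CDS`, `known_exon`, `pseudoexon_<tier>`.
#'
#' @param gene_model a `gene_model`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_gene_model <- function(gene_model, path) {
  gm <- gene_model
  rows <- rbind(
    data.frame(feature = "exon", start = gm$exons$start, end = gm$exons$end),
    data.frame(feature = "CDS", start = gm$cds_start, end = gm$cds_end),
    data.frame(feature = "known_exon", start = gm$known_exons$start,
               end = gm$known_exons$end),
    if (!is.null(gm$pseudoexons)) {
      data.frame(feature = paste0("pseudoexon_", gm$pseudoexons$pe),
                 start = gm$pseudoexons$acceptor_pos,
                 end = gm$pseudoexons$donor_pos)
    })
  out <- data.frame(gene = gm$gene, contig = gm$contig, strand = gm$strand,
                    rows, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 6-column gene-model TSV
#'
#' @param path file written by [write_gene_model()].
#' @return a `gene_model`.
#' @export
read_gene_model <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  ex <- tab[tab$feature == "exon", c("start", "end")]
  ex <- ex[order(ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  cds <- tab[tab$feature == "CDS", ]
  ke <- tab[tab$feature == "known_exon", c("start", "end")]
  rownames(ke) <- NULL
  pe_rows <- tab[grepl("^pseudoexon_", tab$feature), ]
  pes <- if (nrow(pe_rows) > 0L) {
    data.frame(pe = sub("^pseudoexon_", "", pe_rows$feature),
               acceptor_pos = pe_rows$start, donor_pos = pe_rows$end,
               length = pe_rows$end - pe_rows$start,
               tier = NA_character_, annotated = NA,
               stringsAsFactors = FALSE)
  }
  structure(list(gene = tab$gene[1], contig = tab$contig[1],
                 strand = tab$strand[1], exons = ex,
                 cds_start = cds$start[1], cds_end = cds$end[1],
                 known_exons = ke, pseudoexons = pes),
            class = "gene_model")
}

#' Write a variant set as multi-sample VCF 4.2
#'
#' Coordinate-sorted, 1-based; population MAF in INFO key `AF_POPMAX`
#' (omitted where missing), site VAF in INFO key `VAF`, genotypes as GT.
#'
#' @param gset a `variant_set`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_vcf <- function(gset, path) {
  v <- gset$variants
  ids <- colnames(gset$geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pexscan",
    sprintf("##contig=<ID=%s>", unique(v$contig)),
    '##INFO=<ID=AF_POPMAX,Number=1,Type=Float,Description="Population minor allele frequency">',
    '##INFO=<ID=VAF,Number=1,Type=Float,Description="Site variant allele fraction">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")), con)
  info <- ifelse(is.na(v$maf),
                 sprintf("VAF=%s", format(v$vaf, trim = TRUE)),
                 sprintf("AF_POPMAX=%s;VAF=%s",
                         format(v$maf, scientific = FALSE, trim = TRUE,
                                digits = 6),
                         format(v$vaf, trim = TRUE)))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gset$geno + 1L],
                   nrow = nrow(gset$geno))
  gt_str[is.na(gset$geno)] <- "./."
  body <- cbind(v$contig, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                "GT", gt_str)
  write.table(body, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a multi-sample VCF into a variant set
#'
#' Parses genotypes and the `AF_POPMAX`/`VAF` INFO keys (key names
#' configurable). Multiallelic records are not decomposed here; the
#' simulator only emits biallelic sites.
#'
#' @param path VCF file.
#' @param maf_key,vaf_key INFO keys for population MAF and site VAF.
#' @return list of class `variant_set` with `variants` and `geno`.
#' @export
read_vcf <- function(path, maf_key = "AF_POPMAX", vaf_key = "VAF") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    as.numeric(vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
                      character(1)))
  }
  variants <- data.frame(
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    maf = info_field(fix$INFO, maf_key),
    vaf = info_field(fix$INFO, vaf_key),
    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf)
  geno <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = list(NULL, colnames(gt)))
  geno[gt %in% c("0/0", "0|0")] <- 0L
  geno[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  geno[gt %in% c("1/1", "1|1")] <- 2L
  rownames(geno) <- variant_key(variants)
  structure(list(variants = variants, geno = geno),
            class = "variant_set")
}

#' Write junction counts as STAR-dialect TSV
#'
#' Five headerless columns: contig, intron start, intron end (1-based
#' first/last intronic base), strand, unique read count.
#'
#' @param counts junction data.frame.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_junctions <- function(counts, path) {
  write.table(counts[, c("contig", "intron_start", "intron_end", "strand",
                         "unique_count")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a STAR-dialect junction TSV
#'
#' @param path file with the 5 columns of [write_junctions()].
#' @return junction data.frame.
#' @export
read_junctions <- function(path) {
  read.table(path, sep = "\t", stringsAsFactors = FALSE,
             col.names = c("contig", "intron_start", "intron_end",
                           "strand", "unique_count"))
}

#' Write pseudoexon candidates as BED6
#'
#' @param candidates output of [find_partners()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_candidate_bed <- function(candidates, path) {
  bed <- data.frame(candidates$contig, candidates$acceptor_pos,
                    candidates$donor_pos,
                    sprintf("pe_cand_rank%d", candidates$rank),
                    round(candidates$combined_score * 10),
                    "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
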