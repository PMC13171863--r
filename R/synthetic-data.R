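#' Generate a toy genome and gene model with planted pseudoexon decoys
#'
#' Builds a deterministic two-contig genome (a gene-bearing contig and a
#' neutral background contig) and a five-exon gene model whose fourth intron
#' carries three planted pseudoexon decoys, emulating a locus where a long
#' intron hides cryptic splice sites:
#' \itemize{
#'   \item PE1 and PE2: acceptor + donor pairs that score above the
#'     activation threshold already on the reference allele (PE2 is also
#'     recorded as an annotated exon), so downstream candidate search is
#'     never a single-candidate triviality;
#'   \item PE3: a weak decoy donor whose +5 base is the non-consensus A,
#'     paired with an acceptor `acceptor_offset` nt upstream. The +5 A>G
#'     substitution (the planted causal variant) lifts the donor score
#'     across the activation threshold.
#' }
#' The canonical CDS is planted free of premature stop codons so consequence
#' annotation has a clean open reading frame to work from.
#'
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @param intron_length length of intron 4 in bp (>= 1000).
#' @param acceptor_offset distance from the PE3 acceptor boundary to the PE3
#'   donor boundary — the planted pseudoexon length in nt (default 139).
#' @param variant_offset 1-based offset of the causal variant into intron 4
#'   (position +N of the intron; default 4629, i.e. donor +5 of a decoy
#'   4624 nt into the intron).
#' @param contig_length length of each contig in bp.
#' @param activation_threshold donor log2 score that separates the planted
#'   weak (ref) from the activated (alt) decoy donor.
#' @param models splice models used to verify the planted decoy
#'   (default [default_splice_models()]).
#' @return list of class `reference_set`: `genome` (named character vector),
#'   `gene_model` (class `gene_model`), `truth` (causal variant + planted
#'   pseudoexon).
#' @export
make_reference <- function(seed = 1L, intron_length = 8000L,
                           acceptor_offset = 139L, variant_offset = 4629L,
                           contig_length = 200000L,
                           activation_threshold = 10,
                           models = default_splice_models()) {
  if (intron_length < 1000L) stop("intron_length must be >= 1000")
  if (variant_offset >= intron_length) {
    stop("invalid decoy parameters: variant offset must be smaller than the intron length")
  }
  if (acceptor_offset >= variant_offset - 30L) {
    stop("invalid decoy parameters: acceptor offset must leave room upstream of the decoy donor")
  }
  if (acceptor_offset < 25L) stop("acceptor_offset must be >= 25")

  exons <- data.frame(
    start = c(50000L, 52000L, 54000L, 56000L, 56240L + intron_length),
    end   = c(50200L, 52150L, 54180L, 56240L, 56390L + intron_length))
  if (max(exons$end) + 5000L > contig_length) {
    stop("contig_length too small for the requested intron_length")
  }
  cds_start <- 50050L
  cds_end <- exons$start[5] + 96L  # exonic CDS length 816 = 272 codons

  intron4_start <- exons$end[4]
  pe3_donor <- intron4_start + variant_offset - 5L
  pe3_acceptor <- pe3_donor - acceptor_offset
  span <- pe3_acceptor - 20L - intron4_start
  pe1_acceptor <- intron4_start + max(30L, as.integer(round(0.22 * span)))
  pe2_acceptor <- intron4_start + max(160L, as.integer(round(0.55 * span)))
  pe1_donor <- pe1_acceptor + 100L
  pe2_donor <- pe2_acceptor + 120L
  windows <- rbind(c(pe1_acceptor - 20L, pe1_donor + 6L),
                   c(pe2_acceptor - 20L, pe2_donor + 6L),
                   c(pe3_acceptor - 20L, pe3_donor + 6L))
  if (any(windows[, 1] <= intron4_start) ||
      any(windows[, 2] >= exons$start[5]) ||
      any(windows[-nrow(windows), 2] >= windows[-1, 1])) {
    stop("invalid decoy parameters: planted pseudoexons do not fit in the intron")
  }

  acc20 <- "TTCCTTCTTTCCTTCTCTAG"  # pyrimidine tract ending in the invariant AG
  donor_strong <- "CAGGTAAGT"

  with_seed(seed, {
    gene_seq <- random_dna(contig_length)
    bg_seq <- random_dna(contig_length)

    # canonical splice signals
    for (i in 1:4) {
      gene_seq <- plant_motif(gene_seq, exons$end[i] - 3L, donor_strong)
    }
    for (i in 2:5) {
      gene_seq <- plant_motif(gene_seq, exons$start[i] - 20L, acc20)
    }

    # clean open reading frame across the coding exon parts
    cds_pos <- coding_positions(exons, cds_start, cds_end)
    orf <- paste0("ATG",
                  paste(sample_nonstop_codons(length(cds_pos) / 3L - 2L),
                        collapse = ""),
                  "TAA")
    gene_seq <- write_positions(gene_seq, cds_pos, orf)
    fixed <- planted_exonic_positions(exons)
    gene_seq <- repair_orf_stops(gene_seq, cds_pos, fixed)

    # pseudoexon decoys
    for (a in c(pe1_acceptor, pe2_acceptor, pe3_acceptor)) {
      gene_seq <- plant_motif(gene_seq, a - 20L, acc20)
    }
    gene_seq <- plant_motif(gene_seq, pe1_donor - 3L, donor_strong)
    gene_seq <- plant_motif(gene_seq, pe2_donor - 3L, donor_strong)

    # search for a weak donor 9-mer: ref below, +5 A>G alt above threshold
    weak <- pick_weak_donor(models$donor, activation_threshold)
    gene_seq <- plant_motif(gene_seq, pe3_donor - 3L, weak)
  })

  pseudoexons <- data.frame(
    pe = c("PE1", "PE2", "PE3"),
    acceptor_pos = c(pe1_acceptor, pe2_acceptor, pe3_acceptor),
    donor_pos = c(pe1_donor, pe2_donor, pe3_donor),
    length = c(100L, 120L, acceptor_offset),
    tier = c("strong-ref", "strong-ref", "weak-ref"),
    annotated = c(FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)

  gene_model <- structure(list(
    gene = "GENE1", contig = "chr_gene", strand = "+",
    exons = exons, cds_start = cds_start, cds_end = cds_end,
    known_exons = rbind(exons,
                        data.frame(start = pe2_acceptor, end = pe2_donor)),
    pseudoexons = pseudoexons), class = "gene_model")

  vpos0 <- pe3_donor + 4L
  truth <- list(
    causal = data.frame(contig = "chr_gene", pos = vpos0 + 1L,
                        ref = "A", alt = "G", stringsAsFactors = FALSE),
    pseudoexon = pseudoexons[pseudoexons$pe == "PE3", ],
    seed = seed)

  structure(list(genome = c(chr_gene = gene_seq, chr_bg = bg_seq),
                 gene_model = gene_model, truth = truth),
            class = "reference_set")
}

# 0-based genomic positions of coding bases, transcript order (+ strand).
coding_positions <- function(exons, cds_start, cds_end) {
  unlist(lapply(seq_len(nrow(exons)), function(i) {
    s <- max(exons$start[i], cds_start)
    e <- min(exons$end[i], cds_end)
    if (s < e) s:(e - 1L) else integer()
  }))
}

sample_nonstop_codons <- function(n) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  sample(codons, n, replace = TRUE)
}

write_positions <- function(seq, pos0, replacement) {
  stopifnot(length(pos0) == nchar(replacement))
  chars <- strsplit(seq, "")[[1]]
  chars[pos0 + 1L] <- strsplit(replacement, "")[[1]]
  paste(chars, collapse = "")
}

# Exonic bases occupied by planted donor 9-mers (last 3 bases of internal exons).
planted_exonic_positions <- function(exons) {
  unlist(lapply(exons$end[-nrow(exons)], function(e) (e - 3L):(e - 1L)))
}

# Replace any internal in-frame stop codon by setting one of its free
# (non-planted) bases to C: no stop codon contains C.
repair_orf_stops <- function(seq, cds_pos, fixed_pos) {
  repeat {
    chars <- strsplit(seq, "")[[1]]
    cds <- paste(chars[cds_pos + 1L], collapse = "")
    n_codon <- nchar(cds) / 3L
    codons <- substring(cds, 3L * (seq_len(n_codon) - 1L) + 1L,
                        3L * seq_len(n_codon))
    bad <- which(codons %in% c("TAA", "TAG", "TGA"))
    bad <- bad[bad > 1L & bad < n_codon]
    if (length(bad) == 0L) return(seq)
    k <- bad[1]
    gpos <- cds_pos[(3L * (k - 1L) + 1L):(3L * k)]
    free <- setdiff(gpos, fixed_pos)
    if (length(free) == 0L) stop("cannot repair ORF stop codon")
    seq <- write_positions(seq, free[1], "C")
  }
}

pick_weak_donor <- function(donor_model, activation_threshold) {
  candidates <- c("CAGGTAAAT", "AAGGTAAAT", "CAGGTAAAA", "TAGGTAAAT",
                  "CAGGTGAAT", "CAGGTAACT", "AAGGTAAAA", "GAGGTAAAT")
  for (w in candidates) {
    alt <- w
    substr(alt, 8L, 8L) <- "G"  # window position +5
    rs <- score_site(donor_model, w)
    as_ <- score_site(donor_model, alt)
    if (!is.na(rs) && !is.na(as_) &&
        rs < activation_threshold && as_ >= activation_threshold && as_ > rs) {
      return(w)
    }
  }
  stop("no planted donor 9-mer satisfies the activation threshold under this model")
}

#' Default six-member pedigree
#'
#' Two unaffected parents (modelled as a generic first-cousin consanguineous
#' union) and `n_affected` affected siblings, mirroring a pedigree where the
#' sequenced members are four affected siblings and their parents.
#'
#' @param n_affected number of affected siblings (default 4).
#' @return data.frame: `id`, `sex`, `affected`, `father`, `mother`.
#' @export
make_pedigree <- function(n_affected = 4L) {
  kids <- paste0("A", seq_len(n_affected))
  ped <- data.frame(
    id = c("P1", "P2", kids),
    sex = c("M", "F", rep(c("M", "F"), length.out = n_affected)),
    affected = c(FALSE, FALSE, rep(TRUE, n_affected)),
    father = c(NA, NA, rep("P1", n_affected)),
    mother = c(NA, NA, rep("P2", n_affected)),
    stringsAsFactors = FALSE)
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  refs <- stats::na.omit(c(ped$father, ped$mother))
  if (!all(refs %in% ped$id)) stop("pedigree parent ids must exist or be NA")
  if (any(ped$id == ped$father | ped$id == ped$mother, na.rm = TRUE)) {
    stop("individual cannot be its own parent")
  }
  invisible(ped)
}

#' Simulate a multi-sample pedigree variant set
#'
#' Produces dense biallelic markers (enabling run-of-homozygosity detection),
#' background variants with population MAFs drawn from a Beta(0.2, 2)
#' distribution truncated to (0, 0.5], and the planted causal variant.
#' Within each shared autozygous segment, affected individuals are
#' homozygous for a common founder haplotype and parents carry one copy of
#' it; at the causal site, affected individuals are homozygous-alt and both
#' parents heterozygous. Each record carries a population MAF annotation
#' (absent for the causal variant, which is missing from frequency
#' databases) and a site-level VAF.
#'
#' Two autozygous segments are planted by default — one on the gene contig
#' containing the causal variant, one on the neutral contig — so shared-HBD
#' intersection has exactly two regions to find.
#'
#' @param ref a `reference_set` from [make_reference()].
#' @param pedigree data.frame from [make_pedigree()].
#' @param n_background number of background variants (>= 0).
#' @param marker_spacing marker grid spacing in bp.
#' @param segments data.frame (`contig`, `start`, `end`, 0-based half-open)
#'   of planted autozygous segments; the first must contain the causal
#'   variant.
#' @param seed RNG seed.
#' @param out_vcf optional path; when given, the set is also written as a
#'   coordinate-sorted multi-sample VCF 4.2.
#' @return list of class `variant_set`: `variants` (data.frame `contig`,
#'   `pos`, `ref`, `alt`, `maf`, `vaf`, `type`), `geno` (sites x individuals
#'   matrix, 0/1/2), `pedigree`, `truth` (causal variant, planted pseudoexon,
#'   segments, seed).
#' @export
simulate_pedigree_vcf <- function(ref, pedigree = make_pedigree(),
                                  n_background = 200L,
                                  marker_spacing = 2000L,
                                  segments = data.frame(
                                    contig = c("chr_gene", "chr_bg"),
                                    start = c(40000L, 100000L),
                                    end = c(120000L, 160000L)),
                                  seed = 7L, out_vcf = NULL) {
  if (n_background < 0L) stop("n_background must be >= 0")
  validate_pedigree(pedigree)
  if (!any(pedigree$affected)) stop("pedigree has no affected individuals")
  causal <- ref$truth$causal
  in_first <- segments$contig[1] == causal$contig &
    segments$start[1] <= causal$pos - 1L & causal$pos - 1L < segments$end[1]
  if (!in_first) stop("first planted segment must contain the causal variant")

  ids <- pedigree$id
  affected <- ids[pedigree$affected]
  parents <- unique(stats::na.omit(c(pedigree$father[pedigree$affected],
                                     pedigree$mother[pedigree$affected])))
  contigs <- names(ref$genome)
  clen <- nchar(ref$genome[[1]])

  in_segment <- function(contig, pos0) {
    any(segments$contig == contig & segments$start <= pos0 &
          pos0 < segments$end)
  }

  with_seed(seed, {
    rows <- list()
    genos <- list()
    add_site <- function(contig, pos, refb, altb, maf, type, forced = NULL) {
      pos0 <- pos - 1L
      g <- integer(length(ids))
      names(g) <- ids
      if (!is.null(forced)) {
        g[names(forced)] <- forced
      } else if (in_segment(contig, pos0)) {
        f <- rbinom(1L, 1L, maf)
        g[affected] <- 2L * f
        g[parents] <- f + rbinom(length(parents), 1L, maf)
        others <- setdiff(ids, c(affected, parents))
        g[others] <- rbinom(length(others), 2L, maf)
      } else {
        g[] <- rbinom(length(ids), 2L, maf)
      }
      if (any(g == 1L)) {
        vaf <- round(rbeta(1L, 30L, 30L), 3)
      } else {
        vaf <- round(rbeta(1L, 60L, 3L), 3)
      }
      if (type != "causal" && runif(1L) < 0.03) {
        vaf <- round(runif(1L, 0.05, 0.19), 3)
      }
      if (type == "causal") vaf <- 0.5
      rows[[length(rows) + 1L]] <<- data.frame(
        contig = contig, pos = pos, ref = refb, alt = altb,
        maf = maf, vaf = vaf, type = type, stringsAsFactors = FALSE)
      genos[[length(genos) + 1L]] <<- g
    }

    other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

    for (ctg in contigs) {
      for (pos in seq(5001L, clen - 5000L, by = marker_spacing)) {
        if (ctg == causal$contig && pos == causal$pos) next
        rb <- subseq0(ref$genome[[ctg]], pos - 1L, pos)
        add_site(ctg, pos, rb, other_base(rb), runif(1L, 0.2, 0.5), "marker")
      }
    }

    n_bg <- 0L
    while (n_bg < n_background) {
      ctg <- sample(contigs, 1L)
      pos <- sample.int(clen - 10000L, 1L) + 5000L
      if (ctg == causal$contig && abs(pos - causal$pos) < 50L) next
      rb <- subseq0(ref$genome[[ctg]], pos - 1L, pos)
      maf <- 0
      while (maf <= 0 || maf > 0.5) maf <- rbeta(1L, 0.2, 2L)
      add_site(ctg, pos, rb, other_base(rb), maf, "background")
      n_bg <- n_bg + 1L
    }

    forced <- c(stats::setNames(rep(2L, length(affected)), affected),
                stats::setNames(rep(1L, length(parents)), parents))
    add_site(causal$contig, causal$pos, causal$ref, causal$alt,
             NA_real_, "causal", forced = forced)

    variants <- do.call(rbind, rows)
    geno <- do.call(rbind, genos)
    ord <- order(variants$contig, variants$pos)
    variants <- variants[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
    rownames(variants) <- NULL
    rownames(geno) <- variant_key(variants)
  })

  truth <- c(ref$truth, list(segments = segments,
                             marker_spacing = marker_spacing,
                             sim_seed = seed))
  gset <- structure(list(variants = variants, geno = geno,
                         pedigree = pedigree, truth = truth),
                    class = "variant_set")
  if (!is.null(out_vcf)) write_vcf(gset, out_vcf)
  gset
}

#' Simulate splice-junction counts for a mixture of isoforms
#'
#' Draws isoform molecule counts from a multinomial over the supplied
#' proportions, then thins each junction's count through a Poisson with the
#' given capture rate (each isoform contributes to every junction it
#' spans, so the inclusion/exclusion ratio is an unbiased PSI estimand).
#' Isoform labels are `"canonical"` or `"+PE1"`, `"+PE1+PE3"`, ... naming
#' planted pseudoexons of the gene model inserted into the long intron.
#'
#' @param gene_model a `gene_model` with a `pseudoexons` table.
#' @param isoform_props named numeric vector of isoform proportions
#'   (must sum to 1).
#' @param depth expected total molecule count (> 0).
#' @param seed RNG seed.
#' @param capture_rate junction read capture rate in (0, 1].
#' @return data.frame of class `junction_counts`: `contig`, `intron_start`,
#'   `intron_end` (1-based first/last intronic base), `strand`,
#'   `unique_count`; attribute `truth_psi` gives the generating inclusion
#'   proportion per pseudoexon.
#' @export
simulate_junctions <- function(gene_model, isoform_props, depth, seed = 1L,
                               capture_rate = 0.9) {
  if (depth <= 0) stop("depth must be positive")
  if (abs(sum(isoform_props) - 1) > 1e-9) {
    stop("isoform proportions must sum to 1")
  }
  pes <- gene_model$pseudoexons
  n_ex <- nrow(gene_model$exons)
  flank5 <- gene_model$exons[n_ex - 1L, ]
  flank3 <- gene_model$exons[n_ex, ]

  iso_junctions <- lapply(names(isoform_props), function(label) {
    pe_names <- setdiff(strsplit(label, "\\+")[[1]], c("", "canonical"))
    if (!all(pe_names %in% pes$pe)) {
      stop("unknown pseudoexon in isoform label: ", label)
    }
    segs <- pes[match(pe_names, pes$pe), , drop = FALSE]
    segs <- segs[order(segs$acceptor_pos), , drop = FALSE]
    left_ends <- c(flank5$end, segs$donor_pos)
    right_starts <- c(segs$acceptor_pos, flank3$start)
    data.frame(intron_start = left_ends + 1L, intron_end = right_starts,
               stringsAsFactors = FALSE)
  })
  names(iso_junctions) <- names(isoform_props)

  all_j <- unique(do.call(rbind, iso_junctions))
  with_seed(seed, {
    n_iso <- as.vector(rmultinom(1L, size = round(depth), prob = isoform_props))
    names(n_iso) <- names(isoform_props)
    lambda <- numeric(nrow(all_j))
    for (label in names(iso_junctions)) {
      hit <- match(paste(iso_junctions[[label]]$intron_start,
                         iso_junctions[[label]]$intron_end),
                   paste(all_j$intron_start, all_j$intron_end))
      lambda[hit] <- lambda[hit] + n_iso[[label]]
    }
    counts <- rpois(length(lambda), lambda * capture_rate)
  })

  res <- data.frame(contig = gene_model$contig,
                    intron_start = all_j$intron_start,
                    intron_end = all_j$intron_end,
                    strand = gene_model$strand,
                    unique_count = counts,
                    stringsAsFactors = FALSE)
  res <- res[order(res$intron_start, res$intron_end), , drop = FALSE]
  rownames(res) <- NULL
  truth_psi <- vapply(pes$pe, function(p) {
    sum(isoform_props[grepl(paste0("\\+", p, "(\\+|$)"),
                            names(isoform_props))])
  }, numeric(1))
  attr(res, "truth_psi") <- truth_psi
  class(res) <- c("junction_counts", class(res))
  res
}
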