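test_that("reference generation is byte-identical under a fixed seed", {
  ref2 <- make_reference(seed = 1)
  expect_identical(REF$genome, ref2$genome)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(REF$genome, f1)
  write_fasta(ref2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(REF$genome, make_reference(seed = 2)$genome))
})

test_that("planted pseudoexon has the configured length and a valid gene model", {
  expect_equal(REF$truth$pseudoexon$length, 139L)
  expect_equal(REF$truth$pseudoexon$donor_pos - REF$truth$pseudoexon$acceptor_pos,
               139L)
  ref_alt <- make_reference(seed = 3, acceptor_offset = 200L)
  expect_equal(ref_alt$truth$pseudoexon$length, 200L)
  ex <- REF$gene_model$exons
  expect_gte(nrow(ex), 5)
  expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)])) # sorted, non-overlapping
  expect_true(REF$gene_model$cds_start >= min(ex$start))
  expect_true(REF$gene_model$cds_end <= max(ex$end))
  expect_equal(length(REF$genome), 2L)
})

test_that("planted decoy donor crosses the activation threshold only on the alt allele", {
  v <- REF$truth$causal
  d <- REF$truth$pseudoexon$donor_pos
  ref_win <- substr(REF$genome[["chr_gene"]], d - 2, d + 6)
  alt_win <- ref_win
  substr(alt_win, 8, 8) <- "G"  # donor +5
  expect_equal(substr(ref_win, 8, 8), "A")
  expect_equal(d + 5L, v$pos)  # variant sits at donor +5 (1-based)
  expect_lt(score_site(MODELS$donor, ref_win), 10)
  expect_gte(score_site(MODELS$donor, alt_win), 10)
})

test_that("invalid decoy geometry is rejected", {
  expect_error(make_reference(intron_length = 900), "intron_length")
  expect_error(make_reference(intron_length = 4000, variant_offset = 4629),
               "decoy")
  expect_error(make_reference(acceptor_offset = 4620, variant_offset = 4629),
               "decoy")
})

test_that("simulated pedigree VCF has the forced causal genotype configuration", {
  ck <- GSET$variants$type == "causal"
  expect_equal(sum(ck), 1L)
  g <- GSET$geno[ck, ]
  expect_equal(unname(g[c("A1", "A2", "A3", "A4")]), rep(2L, 4))
  expect_equal(unname(g[c("P1", "P2")]), rep(1L, 2))
  # coordinate sorted, MAF present for every non-causal record
  v <- GSET$variants
  expect_false(is.unsorted(order(v$contig, v$pos)))
  expect_true(all(!is.na(v$maf[v$type != "causal"])))
  expect_true(is.na(v$maf[ck]))
  expect_true(all(v$maf <= 0.5, na.rm = TRUE))
})

test_that("simulation is deterministic and rejects invalid input", {
  g2 <- simulate_pedigree_vcf(REF, n_background = 200, seed = 7)
  expect_identical(GSET$variants, g2$variants)
  expect_identical(GSET$geno, g2$geno)
  ped <- make_pedigree()
  ped$affected <- FALSE
  expect_error(simulate_pedigree_vcf(REF, pedigree = ped, seed = 1),
               "affected")
  expect_error(simulate_pedigree_vcf(REF, n_background = -1), "n_background")
})

test_that("causal variant survives the recessive segregation filter", {
  surv <- segregation_filter(GSET$variants, GSET$geno, GSET$pedigree)
  expect_true(causal_key(REF) %in% variant_keys_of(surv))
})

test_that("ROH detection recovers the planted autozygous segment", {
  seg <- GSET$truth$segments[1, ]
  all_roh <- list()
  for (id in c("A1", "A2", "A3", "A4")) {
    roh <- detect_roh(GSET, id, min_length = 50000, max_het = 1,
                      min_markers = 10)
    all_roh[[id]] <- roh
    ro <- max(vapply(seq_len(nrow(roh)), function(i) {
      if (roh$contig[i] != seg$contig) return(0)
      reciprocal_overlap(roh$start[i], roh$end[i], seg$start, seg$end)
    }, numeric(1)))
    # single-individual runs over-extend through chance homozygosity
    expect_gte(ro, 0.8)
  }
  # the cross-sib intersection trims the chance extensions
  hbd <- intersect_hbd(do.call(rbind, all_roh), min_length = 50000)
  shared_ro <- max(vapply(seq_len(nrow(hbd)), function(j) {
    if (hbd$contig[j] != seg$contig) return(0)
    reciprocal_overlap(hbd$start[j], hbd$end[j], seg$start, seg$end)
  }, numeric(1)))
  expect_gte(shared_ro, 0.9)
})

test_that("junction simulation respects isoform proportions", {
  gm <- REF$gene_model
  j_can <- simulate_junctions(gm, c(canonical = 1.0), depth = 1000, seed = 3)
  expect_equal(nrow(j_can), 1L)  # only the exclusion junction
  expect_true(all(j_can$unique_count >= 0))
  expect_equal(unname(attr(j_can, "truth_psi")["PE3"]), 0)
  j_pe <- simulate_junctions(gm, c("+PE3" = 1.0), depth = 1000, seed = 3)
  expect_equal(nrow(j_pe), 2L)   # the two inclusion junctions
  expect_equal(unname(attr(j_pe, "truth_psi")["PE3"]), 1)
  expect_error(simulate_junctions(gm, c(canonical = 0.6, "+PE3" = 0.5),
                                  depth = 100), "sum to 1")
  expect_error(simulate_junctions(gm, c(canonical = 1.0), depth = -5),
               "positive")
  j_a <- simulate_junctions(gm, c(canonical = 0.5, "+PE3" = 0.5),
                            depth = 1e4, seed = 9)
  j_b <- simulate_junctions(gm, c(canonical = 0.5, "+PE3" = 0.5),
                            depth = 1e4, seed = 9)
  expect_identical(j_a, j_b)
})

test_that("packaged cohort table matches its documented shape", {
  tab <- table1_fixture()
  expect_equal(nrow(tab), 29L)
  expect_equal(length(unique(tab$family_id)), 28L)
  alb2 <- tab[tab$family_id == "ALB2", ]
  expect_equal(alb2$gene, "TYR")
  expect_equal(alb2$cdna, "c.1366+4629 A > G")
  # one family contributes two rows
  expect_equal(sum(tab$family_id == "F-ALB7"), 2L)
})
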