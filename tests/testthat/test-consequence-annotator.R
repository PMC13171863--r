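pe_interval <- function(pe) {
  data.frame(start = pe$acceptor_pos, end = pe$donor_pos)
}

test_that("canonical isoform is the exon concatenation", {
  iso <- build_isoform(REF$genome, REF$gene_model)
  ex <- REF$gene_model$exons
  manual <- paste(vapply(seq_len(nrow(ex)), function(i) {
    substr(REF$genome[["chr_gene"]], ex$start[i] + 1L, ex$end[i])
  }, character(1)), collapse = "")
  expect_identical(iso$seq, manual)
  expect_equal(iso$junctions, cumsum(ex$end - ex$start)[-nrow(ex)])
})

test_that("pseudoexon insertion adds its length and respects genomic order", {
  gm <- REF$gene_model
  pes <- gm$pseudoexons
  can <- build_isoform(REF$genome, gm)
  pe3 <- build_isoform(REF$genome, gm, pe_interval(pes[pes$pe == "PE3", ]))
  expect_equal(nchar(pe3$seq), nchar(can$seq) + 139L)
  # input order of pseudoexons does not matter
  both_a <- build_isoform(REF$genome, gm,
                          rbind(pe_interval(pes[pes$pe == "PE1", ]),
                                pe_interval(pes[pes$pe == "PE3", ])))
  both_b <- build_isoform(REF$genome, gm,
                          rbind(pe_interval(pes[pes$pe == "PE3", ]),
                                pe_interval(pes[pes$pe == "PE1", ])))
  expect_identical(both_a$seq, both_b$seq)
  expect_equal(nchar(both_a$seq), nchar(can$seq) + 139L + 100L)
  expect_true(all(diff(both_a$segments$start) > 0))
  # overlapping insertions are rejected
  expect_error(
    build_isoform(REF$genome, gm,
                  data.frame(start = c(60000L, 60050L),
                             end = c(60100L, 60150L))),
    "overlap")
  # a pseudoexon overlapping an exon is rejected
  expect_error(
    build_isoform(REF$genome, gm,
                  data.frame(start = gm$exons$start[2] - 10L,
                             end = gm$exons$start[2] + 10L)),
    "intron")
})

test_that("139-nt insertion shifts the frame after the last exon-4 residue", {
  gm <- REF$gene_model
  pes <- gm$pseudoexons
  iso <- build_isoform(REF$genome, gm, pe_interval(pes[pes$pe == "PE3", ]))
  rep <- annotate_consequence(iso, gm)
  expect_equal(rep$frame_status, "frameshift")  # 139 %% 3 == 1
  expect_equal(rep$inserted_len, 139L)
  # CDS bases in exons 1-4, computed independently from the model layout
  cds_up <- sum(pmin(gm$exons$end[1:4], gm$cds_end) -
                  pmax(gm$exons$start[1:4], gm$cds_start))
  expect_equal(rep$last_canonical_aa, cds_up %/% 3L)
  expect_true(rep$ptc_present)
  can_rep <- annotate_consequence(build_isoform(REF$genome, gm), gm)
  expect_false(can_rep$ptc_present)
  expect_equal(nchar(can_rep$protein), 271L)  # 816-nt CDS minus stop
})

test_that("in-frame stop-free insertions preserve the downstream protein", {
  gm <- REF$gene_model
  can_prot <- annotate_consequence(build_isoform(REF$genome, gm), gm)$protein
  intron4 <- c(gm$exons$end[4], gm$exons$start[5])
  set.seed(77)
  found <- 0L
  while (found < 5L) {
    len <- 3L * sample(10:60, 1)
    start <- sample((intron4[1] + 50L):(intron4[2] - 700L), 1)
    iso <- build_isoform(REF$genome, gm,
                         data.frame(start = start, end = start + len))
    rep <- annotate_consequence(iso, gm)
    # insertion frame must stay stop-free for the property to apply
    ins_seq <- substr(REF$genome[["chr_gene"]], start + 1L, start + len)
    cds_up <- sum(pmin(gm$exons$end[1:4], gm$cds_end) -
                    pmax(gm$exons$start[1:4], gm$cds_start))
    phase <- cds_up %% 3L
    shifted <- paste0(substr(REF$genome[["chr_gene"]],
                             gm$exons$end[4] - (3L - phase) %% 3L + 1L,
                             gm$exons$end[4]),
                      ins_seq)
    codons <- substring(shifted, seq(1, nchar(shifted) - 2, 3),
                        seq(3, nchar(shifted), 3))
    if (any(codons %in% c("TAA", "TAG", "TGA"))) next
    found <- found + 1L
    expect_equal(rep$frame_status, "in-frame")
    expect_equal(nchar(rep$protein), nchar(can_prot) + len / 3L)
    # canonical C-terminus is preserved
    n_tail <- nchar(can_prot) - rep$last_canonical_aa
    expect_equal(substr(rep$protein, nchar(rep$protein) - n_tail + 1L,
                        nchar(rep$protein)),
                 substr(can_prot, rep$last_canonical_aa + 1L,
                        nchar(can_prot)))
  }
})

test_that("translation agrees with an independent codon-table oracle", {
  aa1 <- c(TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
           CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
           GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
           TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
           ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
           GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
           CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
           AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
           TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
           CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
           GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  translate_oracle <- function(cds) {
    n <- nchar(cds) %/% 3L
    out <- character(0)
    for (k in seq_len(n)) {
      aa <- aa1[[substr(cds, 3 * k - 2, 3 * k)]]
      if (aa == "*") break
      out <- c(out, aa)
    }
    paste(out, collapse = "")
  }
  gm <- REF$gene_model
  intron4 <- c(gm$exons$end[4], gm$exons$start[5])
  set.seed(13)
  for (i in 1:20) {
    len <- sample(30:300, 1)
    start <- sample((intron4[1] + 50L):(intron4[2] - 700L), 1)
    iso <- build_isoform(REF$genome, gm,
                         data.frame(start = start, end = start + len))
    rep <- annotate_consequence(iso, gm)
    cds_tx_start <- sum(gm$cds_start - gm$exons$start[1]) + 1L
    cds_seq <- substr(iso$seq, cds_tx_start, nchar(iso$seq))
    expect_identical(rep$protein, translate_oracle(cds_seq))
  }
})

test_that("NMD follows the 50-nt last-junction rule", {
  gm <- REF$gene_model
  pes <- gm$pseudoexons
  iso1 <- build_isoform(REF$genome, gm,
                        pe_interval(pes[pes$pe == "PE1", ]))
  rep1 <- annotate_consequence(iso1, gm)
  # manual junction arithmetic on the fixture
  lens <- iso1$segments$end - iso1$segments$start
  final_junction <- sum(lens[-length(lens)])
  expect_equal(max(iso1$junctions), final_junction)
  if (rep1$ptc_present) {
    manual <- (final_junction - rep1$ptc_tx_pos) >= 50
    expect_equal(predict_nmd(rep1, iso1), manual)
  }
  # PTC absent -> no NMD; reporter context -> not applicable
  can_rep <- annotate_consequence(build_isoform(REF$genome, gm), gm)
  expect_false(predict_nmd(can_rep, build_isoform(REF$genome, gm)))
  expect_true(is.na(predict_nmd(rep1, iso1, no_orf = TRUE)))
})

test_that("a PTC in the last exon escapes NMD", {
  gm <- REF$gene_model
  pes <- gm$pseudoexons
  iso <- build_isoform(REF$genome, gm, pe_interval(pes[pes$pe == "PE3", ]))
  rep <- annotate_consequence(iso, gm)
  fake <- rep
  fake$ptc_tx_pos <- max(iso$junctions) + 10L  # stop inside the last exon
  expect_false(predict_nmd(fake, iso))
  fake$ptc_tx_pos <- max(iso$junctions) - 200L
  expect_true(predict_nmd(fake, iso))
})

test_that("domain impact reports losses downstream of the truncation", {
  rep <- list(last_canonical_aa = 240L)
  class(rep) <- "consequence_report"
  dm <- list(catalytic = c(50, 200), transmembrane = c(250, 262),
             tail = c(263, 271))
  imp <- domain_impact(rep, dm, 271L)
  expect_equal(imp$status, c("retained", "lost", "lost"))
  rep$last_canonical_aa <- 255L
  expect_equal(domain_impact(rep, dm, 271L)$status,
               c("retained", "partly-lost", "lost"))
  rep$last_canonical_aa <- 271L
  expect_true(all(domain_impact(rep, dm, 271L)$status == "retained"))
  # brute force over random truncation points
  set.seed(3)
  for (i in 1:20) {
    rep$last_canonical_aa <- sample(0:271, 1)
    imp <- domain_impact(rep, dm, 271L)
    for (j in seq_along(dm)) {
      expected <- if (rep$last_canonical_aa >= dm[[j]][2]) "retained"
      else if (rep$last_canonical_aa >= dm[[j]][1]) "partly-lost"
      else "lost"
      expect_equal(imp$status[j], expected)
    }
  }
})
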