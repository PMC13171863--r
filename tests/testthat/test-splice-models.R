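test_that("PWM scoring matches closed forms", {
  # consensus-only PWM: each position gives log2(1/0.25) = 2, total 18
  f <- withr::local_tempfile(fileext = ".tsv")
  probs <- matrix(0, nrow = 9, ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  consensus <- c("C", "A", "G", "G", "T", "A", "A", "G", "T")
  probs[cbind(1:9, match(consensus, colnames(probs)))] <- 1
  writeLines(c("pos\tA\tC\tG\tT",
               paste(1:9, probs[, 1], probs[, 2], probs[, 3], probs[, 4],
                     sep = "\t")), f)
  m <- load_model("donor", f)
  expect_equal(score_site(m, "CAGGTAAGT"), 9 * log2(1 / 0.25))

  # single informative position P(G) = 0.5 contributes log2(2) = 1
  f2 <- withr::local_tempfile(fileext = ".tsv")
  rows <- rep("0.25\t0.25\t0.25\t0.25", 9)
  rows[5] <- "0.2\t0.2\t0.5\t0.1"
  writeLines(c("pos\tA\tC\tG\tT", paste(1:9, rows, sep = "\t")), f2)
  m2 <- load_model("donor", f2)
  expect_equal(score_site(m2, "AAAAGAAAA"), 1)
})

test_that("PWM score equals per-position brute force on random windows", {
  tab <- read.table(system.file("extdata", "donor_pwm.tsv",
                                package = "pexscan"),
                    header = TRUE, comment.char = "#")
  set.seed(42)
  for (i in 1:25) {
    win <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
                 collapse = "")
    bases <- strsplit(win, "")[[1]]
    manual <- sum(vapply(1:9, function(p) {
      log2(tab[p, bases[p]] / 0.25)
    }, numeric(1)))
    expect_equal(score_site(MODELS$donor, win), manual)
  }
})

test_that("k-mer table models load, score, and reject incomplete tables", {
  tab <- read.table(system.file("extdata", "donor_pwm.tsv",
                                package = "pexscan"),
                    header = TRUE, comment.char = "#")
  kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 9),
                                       stringsAsFactors = FALSE))
  # score every 9-mer with the PWM so the table path can be cross-checked
  base_idx <- lapply(1:9, function(p) {
    match(substr(kmers, p, p), c("A", "C", "G", "T"))
  })
  lo <- as.matrix(log2(tab[, c("A", "C", "G", "T")] / 0.25))
  scores <- Reduce(`+`, lapply(1:9, function(p) lo[p, ][base_idx[[p]]]))
  f <- withr::local_tempfile(fileext = ".txt")
  write.table(data.frame(kmers, scores), f, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  m <- load_model("donor", f)
  expect_equal(score_site(m, "GAGGTAAGT"),
               score_site(MODELS$donor, "GAGGTAAGT"))

  f_bad <- withr::local_tempfile(fileext = ".txt")
  write.table(data.frame(kmers[1:100], scores[1:100]), f_bad, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_error(load_model("donor", f_bad), "incomplete")
})

test_that("window validation and ambiguity handling", {
  expect_error(score_site(MODELS$donor, "CAGGT"), "length")
  expect_error(score_site(MODELS$acceptor, "CAGGTAAGT"), "length")
  expect_true(is.na(score_site(MODELS$donor, "CAGGTNAGT")))
  # determinism
  expect_identical(score_site(MODELS$donor, "CAGGTAAGT"),
                   score_site(MODELS$donor, "CAGGTAAGT"))
})

test_that("scan_variant enumerates all windows overlapping an SNV", {
  d <- scan_variant(MODELS, REF$genome, REF$truth$causal)
  expect_equal(sum(d$kind == "donor"), 9)
  expect_equal(sum(d$kind == "acceptor"), 23)
  expect_true(all(diff(d$alt_score) <= 0))
  expect_equal(d$delta, d$alt_score - d$ref_score)
})

test_that("swapping ref and alt negates every delta", {
  v <- REF$truth$causal
  d_fwd <- scan_variant(MODELS, REF$genome, v)
  genome_alt <- REF$genome
  g <- genome_alt[[v$contig]]
  substr(g, v$pos, v$pos) <- v$alt
  genome_alt[[v$contig]] <- g
  v_rev <- data.frame(contig = v$contig, pos = v$pos, ref = v$alt,
                      alt = v$ref, stringsAsFactors = FALSE)
  d_rev <- scan_variant(MODELS, genome_alt, v_rev)
  key <- function(d) paste(d$kind, d$win_start)
  d_rev <- d_rev[match(key(d_fwd), key(d_rev)), ]
  expect_equal(d_rev$delta, -d_fwd$delta)
})

test_that("minus-strand scan equals plus-strand scan of the reverse complement", {
  set.seed(11)
  fwd <- paste(sample(c("A", "C", "G", "T"), 101, replace = TRUE),
               collapse = "")
  substr(fwd, 51, 51) <- "A"
  genome_fwd <- c(chrF = fwd)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  genome_rc <- c(chrF = rc)
  v_fwd <- data.frame(contig = "chrF", pos = 51L, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  v_rc <- data.frame(contig = "chrF", pos = 51L, ref = "T", alt = "C",
                     stringsAsFactors = FALSE)
  d_minus <- scan_variant(MODELS, genome_fwd, v_fwd, strand = "-")
  d_plus <- scan_variant(MODELS, genome_rc, v_rc, strand = "+")
  expect_equal(sort(round(d_minus$alt_score, 10)),
               sort(round(d_plus$alt_score, 10)))
  expect_equal(sort(round(d_minus$ref_score, 10)),
               sort(round(d_plus$ref_score, 10)))
})

test_that("scan_variant rejects a reference mismatch", {
  v <- REF$truth$causal
  v$ref <- "C"
  expect_error(scan_variant(MODELS, REF$genome, v), "reference mismatch")
})
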