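#' Splice-site scoring models
#'
#' Donor (5'ss) sites are scored over a 9-mer spanning the last 3 exonic and
#' first 6 intronic bases; acceptor (3'ss) sites over a 23-mer spanning the
#' last 20 intronic bases (ending in the invariant AG) and the first 3 exonic
#' bases. Scores are log2 likelihood ratios against a background model, so
#' higher means a stronger site and 0 means indistinguishable from background.
#'
#' Two parameter formats are supported:
#' \describe{
#'   \item{PWM}{a position weight matrix file with header `pos A C G T` and
#'     one probability row per window position; probabilities per position
#'     must sum to 1. This is the format of the models shipped in
#'     `inst/extdata` (first-order models built from canonical human
#'     splice-site base frequencies).}
#'   \item{k-mer table}{two whitespace-separated columns, k-mer and score
#'     (log2), one row per window sequence — the distribution format of
#'     published maximum-entropy score tables. The table must be complete
#'     for the window length.}
#' }
#'
#' @param kind `"donor"` or `"acceptor"`.
#' @param source path to a parameter file (PWM or k-mer table).
#' @param background per-base background probabilities for PWM models
#'   (default uniform 0.25).
#' @return An object of class `splice_model`.
#' @export
load_model <- function(kind = c("donor", "acceptor"), source,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  kind <- match.arg(kind)
  width <- if (kind == "donor") 9L else 23L
  lines <- readLines(source)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty model file: ", source)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (identical(header, c("pos", "A", "C", "G", "T"))) {
    tab <- read.table(text = lines, header = TRUE, stringsAsFactors = FALSE)
    if (nrow(tab) != width) {
      stop(sprintf("%s PWM must have %d positions, found %d",
                   kind, width, nrow(tab)))
    }
    probs <- t(as.matrix(tab[, c("A", "C", "G", "T")]))
    if (any(abs(colSums(probs) - 1) > 1e-9)) {
      bad <- which(abs(colSums(probs) - 1) > 1e-9)
      stop("PWM position probabilities must sum to 1; offending positions: ",
           paste(tab$pos[bad], collapse = ", "))
    }
    logodds <- log2(probs / background[rownames(probs)])
    model <- list(kind = kind, type = "pwm", width = width,
                  positions = tab$pos, logodds = logodds)
  } else {
    tab <- read.table(text = lines, header = FALSE,
                      col.names = c("kmer", "score"),
                      colClasses = c("character", "numeric"))
    tab$kmer <- toupper(tab$kmer)
    if (any(nchar(tab$kmer) != width)) {
      stop(sprintf("k-mer table for %s model must contain %d-mers", kind, width))
    }
    if (nrow(tab) < 4^width || anyDuplicated(tab$kmer)) {
      present <- unique(tab$kmer)
      missing_n <- 4^width - length(present)
      stop(sprintf(
        "incomplete k-mer table for %s model: %d of %d window sequences missing",
        kind, missing_n, 4^width))
    }
    scores <- tab$score
    names(scores) <- tab$kmer
    model <- list(kind = kind, type = "kmer", width = width, scores = scores)
  }
  class(model) <- "splice_model"
  model
}

#' Load the package's default donor/acceptor models
#'
#' @return list with elements `donor` and `acceptor` (class `splice_model`).
#' @export
default_splice_models <- function() {
  list(
    donor = load_model("donor",
                       system.file("extdata", "donor_pwm.tsv",
                                   package = "pexscan")),
    acceptor = load_model("acceptor",
                          system.file("extdata", "acceptor_pwm.tsv",
                                      package = "pexscan"))
  )
}

#' Score a splice-site window
#'
#' Returns the model's log2 odds score for a window of the model's width.
#' Windows containing non-ACGT characters (e.g. N) score `NA`, never 0:
#' 0 is a meaningful log-odds value.
#'
#' @param model a `splice_model`.
#' @param sequence character window, length must equal `model$width`.
#' @return numeric score (log2), or `NA_real_` for ambiguous windows.
#' @export
score_site <- function(model, sequence) {
  stopifnot(inherits(model, "splice_model"))
  sequence <- toupper(sequence)
  if (nchar(sequence) != model$width) {
    stop(sprintf("window length %d does not match %s model width %d",
                 nchar(sequence), model$kind, model$width))
  }
  if (grepl("[^ACGT]", sequence)) return(NA_real_)
  if (model$type == "pwm") {
    bases <- match(strsplit(sequence, "")[[1]], rownames(model$logodds))
    sum(model$logodds[cbind(bases, seq_len(model$width))])
  } else {
    unname(model$scores[[sequence]])
  }
}

#' Score ref/alt splice-site deltas for a variant
#'
#' Enumerates every donor and acceptor window overlapping a single-nucleotide
#' variant on the requested strand, scores the window under the reference and
#' the alternate allele, and reports `delta = alt - ref` for each, sorted by
#' descending alternate score. Windows containing ambiguous bases are dropped.
#'
#' Boundary columns locate the window's exon/intron boundary in 0-based
#' genomic coordinates: for a donor, the first intronic base; for an acceptor,
#' the first exonic base. These feed [find_partners()].
#'
#' @param models list with `donor` and `acceptor` `splice_model`s.
#' @param genome named character vector of contig sequences.
#' @param variant one-row data.frame with `contig`, `pos` (1-based), `ref`,
#'   `alt` (single bases).
#' @param strand `"+"` or `"-"` — the gene strand to scan.
#' @param both_strands scan both strands.
#' @return data.frame: `kind`, `strand`, `win_start` (0-based), `boundary`,
#'   `ref_seq`, `alt_seq`, `ref_score`, `alt_score`, `delta`.
#' @export
scan_variant <- function(models, genome, variant, strand = "+",
                         both_strands = FALSE) {
  stopifnot(nrow(variant) == 1L)
  contig <- variant$contig
  if (!contig %in% names(genome)) stop("variant contig absent from genome: ", contig)
  seq <- genome[[contig]]
  pos0 <- variant$pos - 1L
  ref_base <- subseq0(seq, pos0, pos0 + 1L)
  if (!identical(toupper(ref_base), toupper(variant$ref))) {
    stop(sprintf("reference mismatch at %s:%d: genome has %s, variant ref is %s",
                 contig, variant$pos, ref_base, variant$ref))
  }
  strands <- if (both_strands) c("+", "-") else strand
  out <- list()
  for (std in strands) {
    for (kind in c("donor", "acceptor")) {
      model <- models[[kind]]
      w <- model$width
      starts <- max(0L, pos0 - w + 1L):min(pos0, nchar(seq) - w)
      for (s in starts) {
        ref_win <- subseq0(seq, s, s + w)
        alt_win <- ref_win
        substr(alt_win, pos0 - s + 1L, pos0 - s + 1L) <- variant$alt
        if (std == "-") {
          ref_win <- revcomp(ref_win)
          alt_win <- revcomp(alt_win)
        }
        rs <- score_site(model, ref_win)
        as_ <- score_site(model, alt_win)
        if (is.na(rs) || is.na(as_)) next
        boundary <- if (std == "+") {
          if (kind == "donor") s + 3L else s + 20L
        } else {
          # mirrored window on the minus strand
          if (kind == "donor") s + w - 3L else s + w - 20L
        }
        out[[length(out) + 1L]] <- data.frame(
          contig = contig, kind = kind, strand = std,
          win_start = s, boundary = boundary,
          ref_seq = ref_win, alt_seq = alt_win,
          ref_score = rs, alt_score = as_, delta = as_ - rs,
          variant = variant_key(variant),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(), kind = character(),
                      strand = character(), win_start = integer(),
                      boundary = integer(), ref_seq = character(),
                      alt_seq = character(), ref_score = numeric(),
                      alt_score = numeric(), delta = numeric(),
                      variant = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$alt_score), , drop = FALSE]
  rownames(res) <- NULL
  res
}
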