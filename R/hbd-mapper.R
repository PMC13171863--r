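#' Detect runs of homozygosity for one individual
#'
#' Greedy run-scan over coordinate-sorted genotype calls: a run accumulates
#' consecutive homozygous markers (hom-ref or hom-alt) and tolerates up to
#' `max_het` heterozygous calls; when the budget is exceeded the run is
#' closed at its last homozygous marker and scanning restarts after the
#' breaking heterozygote, so emitted runs never overlap. Missing calls are
#' skipped and count neither as markers nor as interruptions. Run endpoints
#' are the first/last homozygous marker positions (0-based half-open).
#'
#' Defaults suit real WGS data (1 Mbp, 25 markers); synthetic toy genomes
#' use smaller values (see the package vignette).
#'
#' @param gset list with `variants` (data.frame `contig`, `pos` sorted) and
#'   `geno` (sites x individuals matrix, 0/1/2/NA), as produced by
#'   [simulate_pedigree_vcf()] or [read_vcf()].
#' @param individual column name in `gset$geno`.
#' @param min_length minimum run span in bp.
#' @param max_het heterozygous calls tolerated per run.
#' @param min_markers minimum homozygous+heterozygous markers per run.
#' @return data.frame: `individual`, `contig`, `start`, `end` (0-based
#'   half-open), `n_markers`, `n_het`.
#' @export
detect_roh <- function(gset, individual, min_length = 1e6, max_het = 1L,
                       min_markers = 25L) {
  v <- gset$variants
  if (is.unsorted(order(v$contig, v$pos)) ||
      any(unlist(tapply(v$pos, v$contig, is.unsorted)))) {
    stop("genotypes must be sorted by (contig, pos)")
  }
  g <- gset$geno[, individual]
  out <- list()
  for (ctg in unique(v$contig)) {
    idx <- which(v$contig == ctg & !is.na(g))
    pos <- v$pos[idx]
    gt <- g[idx]
    i <- 1L
    n <- length(idx)
    while (i <= n) {
      if (gt[i] == 1L) { i <- i + 1L; next }
      # start a run at a homozygous marker
      j <- i
      het <- 0L
      last_hom <- i
      break_at <- NA_integer_
      while (j <= n) {
        if (gt[j] == 1L) {
          if (het + 1L > max_het) { break_at <- j; break }
          het <- het + 1L
        } else {
          last_hom <- j
        }
        j <- j + 1L
      }
      n_mark <- last_hom - i + 1L
      n_het_in <- sum(gt[i:last_hom] == 1L)
      span <- pos[last_hom] - pos[i] + 1L
      if (span >= min_length && n_mark >= min_markers) {
        out[[length(out) + 1L]] <- data.frame(
          individual = individual, contig = ctg,
          start = pos[i] - 1L, end = pos[last_hom],
          n_markers = n_mark, n_het = n_het_in,
          stringsAsFactors = FALSE)
      }
      i <- if (is.na(break_at)) n + 1L else break_at + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(individual = character(), contig = character(),
                      start = integer(), end = integer(),
                      n_markers = integer(), n_het = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Intersect homozygous runs across individuals
#'
#' Returns the maximal intervals contained in at least one run of every
#' individual — the shared homozygosity-by-descent regions of a set of
#' affected relatives — retaining those at least `min_length` long.
#'
#' @param segments data.frame of runs for several individuals
#'   (as [detect_roh()] output, possibly row-bound).
#' @param min_length minimum shared-region span in bp.
#' @return data.frame: `contig`, `start`, `end`, `size_mbp`, `members`.
#' @export
intersect_hbd <- function(segments, min_length = 1e6) {
  ids <- unique(segments$individual)
  if (length(ids) < 2L) stop("intersect_hbd needs runs from >= 2 individuals")
  out <- list()
  for (ctg in unique(segments$contig)) {
    per_ind <- lapply(ids, function(id) {
      s <- segments[segments$individual == id & segments$contig == ctg, ]
      IRanges::reduce(IRanges::IRanges(start = s$start + 1L, end = s$end))
    })
    shared <- Reduce(IRanges::intersect, per_ind)
    if (length(shared) == 0L) next
    keep <- IRanges::width(shared) >= min_length
    shared <- shared[keep]
    if (length(shared) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      contig = ctg,
      start = IRanges::start(shared) - 1L,
      end = IRanges::end(shared),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), size_mbp = numeric(),
                      members = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$size_mbp <- region_size_mbp(res$start, res$end)
  res$members <- paste(ids, collapse = ",")
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Region size in Mbp
#'
#' `(end - start) / 1e6`, rounded half-up to 2 decimals — the convention
#' used when reporting shared autozygous regions.
#'
#' @param start,end region boundaries in bp (`end >= start`).
#' @return numeric Mbp with 2 decimals.
#' @export
region_size_mbp <- function(start, end) {
  if (any(end < start)) stop("end must be >= start")
  round_half_up((end - start) / 1e6, 2)
}

#' Write a colour-coded genotype BED9 track
#'
#' Emits one BED9 record per marker, coloured by genotype class (hom-ref
#' blue, het red, hom-alt green), under a `track` header, followed by a
#' second track of the individual's homozygous runs (grey). Coordinates are
#' 0-based half-open. This is the genome-browser track that makes
#' homozygous runs visible by eye.
#'
#' @param gset genotype set (see [detect_roh()]).
#' @param individual column name in `gset$geno`.
#' @param segments run data.frame from [detect_roh()] (may be empty).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_colour_bed <- function(gset, individual, segments, path) {
  cols <- c(`0` = "0,0,255", `1` = "255,0,0", `2` = "0,128,0")
  v <- gset$variants
  g <- gset$geno[, individual]
  keep <- !is.na(g)
  v <- v[keep, , drop = FALSE]
  g <- g[keep]
  name <- c(`0` = "hom-ref", `1` = "het", `2` = "hom-alt")[as.character(g)]
  marker <- data.frame(v$contig, v$pos - 1L, v$pos, name, 0L, ".",
                       v$pos - 1L, v$pos, cols[as.character(g)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track name="%s genotypes" itemRgb="On"', individual), con)
  write.table(marker, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(sprintf('track name="%s ROH" itemRgb="On"', individual), con)
  if (nrow(segments) > 0L) {
    seg <- data.frame(segments$contig, segments$start, segments$end,
                      "roh", 0L, ".", segments$start, segments$end,
                      "128,128,128")
    write.table(seg, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read back a colour-coded BED file
#'
#' Parses a file written by [write_colour_bed()]; used for round-trip checks.
#'
#' @param path BED file.
#' @return list with `markers` and `segments` data.frames (BED9 columns).
#' @export
read_colour_bed <- function(path) {
  lines <- readLines(path)
  track <- grepl("^track", lines)
  block <- cumsum(track)
  parse_block <- function(b) {
    body <- lines[block == b & !track]
    if (length(body) == 0L) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        score = integer(), strand = character(),
                        thick_start = integer(), thick_end = integer(),
                        rgb = character(), stringsAsFactors = FALSE))
    }
    read.table(text = body, sep = "\t", stringsAsFactors = FALSE,
               col.names = c("chrom", "start", "end", "name", "score",
                             "strand", "thick_start", "thick_end", "rgb"))
  }
  list(markers = parse_block(1L), segments = parse_block(2L))
}
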