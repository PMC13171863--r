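#' ACMG/AMP evidence parsing and point-based classification
#'
#' Evidence strings follow the tabular convention `CATEGORY (CODE, CODE, ...)`
#' where `CATEGORY` is one of P, LP, VUS, LB, B and each code is an ACMG/AMP
#' evidence item (PVS1, PS1-4, PM1-6, PP1-5, BA1, BS1-4, BP1-7), optionally
#' carrying a strength modifier suffix: `_sup` (supporting), `_mod`
#' (moderate), `_str` (strong), `_vstr` (very strong). Without a suffix the
#' code's default strength class applies (PVS very strong, PS strong,
#' PM moderate, PP supporting; BA stand-alone, BS strong, BP supporting).
#'
#' @param s evidence string, e.g. `"P (PVS1, PM2_sup, PM3)"`.
#' @return list with `category` (the claimed category) and `codes`, a
#'   data.frame with columns `code`, `strength`, `points` (pathogenic
#'   evidence positive, benign negative).
#' @export
parse_evidence <- function(s) {
  m <- regmatches(s, regexec("^\\s*(P|LP|VUS|LB|B)\\s*\\(([^)]*)\\)\\s*$", s))[[1]]
  if (length(m) == 0L || !nzchar(trimws(m[3]))) {
    stop("malformed ACMG evidence string: ", deparse(s))
  }
  category <- m[2]
  tokens <- trimws(strsplit(m[3], ",")[[1]])
  codes <- lapply(tokens, parse_evidence_code)
  list(category = category, codes = do.call(rbind, codes))
}

parse_evidence_code <- function(token) {
  m <- regmatches(token,
    regexec("^(PVS|PS|PM|PP|BA|BS|BP)([0-9]+)(?:_(sup|mod|str|vstr))?$",
            token))[[1]]
  if (length(m) == 0L) stop("unrecognized ACMG evidence code: ", deparse(token))
  prefix <- m[2]
  suffix <- m[4]
  default_strength <- switch(prefix,
    PVS = "very-strong", PS = "strong", PM = "moderate", PP = "supporting",
    BA = "stand-alone", BS = "strong", BP = "supporting")
  strength <- if (nzchar(suffix)) {
    switch(suffix, sup = "supporting", mod = "moderate", str = "strong",
           vstr = "very-strong")
  } else default_strength
  magnitude <- switch(strength, supporting = 1, moderate = 2, strong = 4,
                      `very-strong` = 8, `stand-alone` = 8)
  sign <- if (prefix %in% c("BA", "BS", "BP")) -1 else 1
  data.frame(code = token, strength = strength, points = sign * magnitude,
             stringsAsFactors = FALSE)
}

#' Combine ACMG evidence codes into a classification
#'
#' Uses the point-based combiner: supporting 1, moderate 2, strong 4,
#' very strong 8 points (benign evidence negative), summed and banded:
#' total >= 10 pathogenic (P), 6-9 likely pathogenic (LP), 0-5 uncertain
#' (VUS), -6..-1 likely benign (LB), <= -7 benign (B).
#'
#' @param codes data.frame as returned in `parse_evidence()$codes`.
#' @return list with `points` (total) and `category`.
#' @export
classify <- function(codes) {
  if (is.null(codes) || nrow(codes) == 0L) stop("no evidence codes supplied")
  total <- sum(codes$points)
  category <- if (total >= 10) "P"
  else if (total >= 6) "LP"
  else if (total >= 0) "VUS"
  else if (total >= -6) "LB"
  else "B"
  list(points = total, category = category)
}

#' Parse and classify an evidence string in one step
#'
#' @inheritParams parse_evidence
#' @return list with `points`, `category` and `claimed` (the category
#'   printed in the string, for cross-checking).
#' @export
classify_string <- function(s) {
  parsed <- parse_evidence(s)
  res <- classify(parsed$codes)
  res$claimed <- parsed$category
  res
}

#' Packaged cohort variant table
#'
#' Returns the packaged table of rare homozygous variants identified in the
#' 28-family consanguineous OCA cohort (29 rows; one family contributes rows
#' for two genes). Columns: `family_id`, `gene`, `cdna`, `protein`, `acmg`
#' (evidence string), `maf` (South Asian population minor allele frequency,
#' `NA` where unavailable), `reference` (`"This study"` or a literature key).
#'
#' @return data.frame with 29 rows.
#' @export
table1_fixture <- function() {
  read.table(system.file("extdata", "cohort_table1.tsv", package = "pexscan"),
             header = TRUE, sep = "\t", quote = "", comment.char = "",
             stringsAsFactors = FALSE)
}

#' Default gene-to-condition map
#'
#' @return data.frame with columns `gene`, `condition` (OCA, HPS, CHS, ...).
#' @export
gene_condition_map <- function() {
  read.table(system.file("extdata", "gene_condition_map.tsv",
                         package = "pexscan"),
             header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Summarize a cohort variant table
#'
#' Computes distinct-family counts per gene with integer percentages
#' (half-up rounding) over distinct families, condition-level family counts
#' via a gene-to-condition map, recurrent-variant family counts keyed on
#' (gene, cDNA), and the count of novel variants (distinct (gene, cDNA)
#' pairs referenced as "This study").
#'
#' @param table data.frame in the layout of [table1_fixture()].
#' @param map gene-to-condition map; default [gene_condition_map()].
#' @return list with `n_families`, `per_gene` (gene, families, pct),
#'   `per_condition` (condition, families, pct), `recurrent`
#'   (gene, cdna, families), `n_novel_variants`.
#' @export
summarize_cohort <- function(table, map = gene_condition_map()) {
  stopifnot(nrow(table) > 0L)
  n_families <- length(unique(table$family_id))
  fam_gene <- unique(table[, c("family_id", "gene")])
  per_gene <- aggregate(family_id ~ gene, fam_gene, function(x) length(unique(x)))
  names(per_gene) <- c("gene", "families")
  per_gene$pct <- round_half_up(100 * per_gene$families / n_families)
  per_gene <- per_gene[order(-per_gene$families, per_gene$gene), ]
  rownames(per_gene) <- NULL

  cond <- map$condition[match(fam_gene$gene, map$gene)]
  if (anyNA(cond)) {
    warning("genes absent from condition map counted as unclassified: ",
            paste(unique(fam_gene$gene[is.na(cond)]), collapse = ", "))
    cond[is.na(cond)] <- "unclassified"
  }
  fam_cond <- unique(data.frame(family_id = fam_gene$family_id,
                                condition = cond, stringsAsFactors = FALSE))
  per_condition <- aggregate(family_id ~ condition, fam_cond,
                             function(x) length(unique(x)))
  names(per_condition) <- c("condition", "families")
  per_condition$pct <- round_half_up(100 * per_condition$families / n_families)

  fam_var <- unique(table[, c("family_id", "gene", "cdna")])
  recurrent <- aggregate(family_id ~ gene + cdna, fam_var,
                         function(x) length(unique(x)))
  names(recurrent) <- c("gene", "cdna", "families")
  recurrent <- recurrent[order(-recurrent$families), ]
  rownames(recurrent) <- NULL

  novel <- unique(table[table$reference == "This study", c("gene", "cdna")])

  list(n_families = n_families,
       per_gene = per_gene,
       per_condition = per_condition,
       recurrent = recurrent,
       n_novel_variants = nrow(novel))
}
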