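---
title: "Discovering and interpreting deep-intronic pseudoexon-activating variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and interpreting deep-intronic pseudoexon-activating variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pexscan)
```

## The problem

In autosomal recessive disorders such as oculocutaneous albinism (OCA), a
substantial fraction of patients carry only one identifiable coding variant
in the implicated gene, suggesting that the second pathogenic allele hides
in non-coding sequence. One recurrent mechanism is *pseudoexon activation*:
an intron contains an exon-like stretch flanked by cryptic splice sites that
are normally too weak to be used. A single-nucleotide variant that
strengthens one of these sites — for example replacing the non-consensus A
at donor position +5 by the consensus G — can switch the pseudoexon on,
disrupting the reading frame of the mature mRNA.

`pexscan` packages the complete inference chain needed to find and interpret
such variants in consanguineous pedigrees:

1. **Variant filtering** (`filter_frequency`, `filter_vaf`, `filter_region`,
   `segregation_filter`): population-frequency, allele-fraction, region and
   recessive-segregation filters. Panel-style region filtering (coding exons
   ± 20 bp) is blind to deep-intronic variants by construction; locus-wide
   filtering is what reaches them.
2. **Autozygosity mapping** (`detect_roh`, `intersect_hbd`,
   `region_size_mbp`, `write_colour_bed`): per-individual runs of
   homozygosity and their intersection across affected relatives — the
   shared homozygosity-by-descent (HBD) regions in which a recessive causal
   variant must lie in a consanguineous family.
3. **Splice-site scoring** (`load_model`, `score_site`, `scan_variant`):
   log2 likelihood-ratio scoring of donor 9-mers and acceptor 23-mers, and
   ref/alt deltas for every window overlapping a variant.
4. **Pseudoexon delineation** (`find_partners`, `annotate_known_exons`):
   partner-site search around an activated splice site, yielding candidate
   pseudoexons with coordinates, length and paired scores.
5. **Consequence annotation** (`build_isoform`, `annotate_consequence`,
   `predict_nmd`, `domain_impact`): reading frame, novel peptide, premature
   termination codons (PTC), nonsense-mediated decay (NMD) and lost protein
   domains for transcripts carrying pseudoexon insertions.
6. **Inclusion quantification** (`compute_psi`, `junctions_to_psi`):
   junction-based percent spliced in.
7. **Cohort interpretation** (`parse_evidence`, `classify`,
   `summarize_cohort`): point-based ACMG/AMP classification and cohort
   statistics.

The exported functions, this vignette and `scripts/acceptance.R` are the
package's interface; each numbered module above maps onto one exported
function group.

## Splice-site models

Donor sites are scored over 9-mers spanning the last 3 exonic and first 6
intronic bases; acceptor sites over 23-mers spanning the last 20 intronic
bases (ending in the invariant AG) and 3 exonic bases. A score is the sum of
per-position log2 odds against a background model, so 0 means
"indistinguishable from background" and typical strong sites score above 10
(donor) under the shipped models.

Two parameterizations load through the same interface:

* **PWM files** (shipped in `inst/extdata`): first-order positional models
  built from canonical human splice-site base frequencies, floored away from
  zero so every ACGT window has a finite score. These drive all synthetic
  analyses.
* **k-mer score tables** in the distribution format of published
  maximum-entropy models: one score per window sequence, checked for
  completeness at load. Users who have the published tables can reproduce
  published maximum-entropy scores through `score_site` directly; the
  package does not ship them.

Windows containing N score `NA`, never 0 — 0 is a meaningful log-odds.
Only the gene strand is scanned by default (`scan_variant(both_strands =
TRUE)` scans both).

## The synthetic study system

Because individual genome data from real pedigrees cannot be redistributed,
every analysis here is exercised end-to-end on synthetic data with recorded
ground truth. `make_reference()` builds a two-contig toy genome (200 kb
gene contig, 200 kb neutral contig) carrying a five-exon gene whose fourth
intron (8 kb by default) contains three planted pseudoexon decoys:

* **PE1** (100 nt) and **PE2** (120 nt): acceptor/donor pairs strong already
  on the reference allele; PE2 is additionally recorded as an annotated
  exon. They guarantee the candidate search is never a single-candidate
  triviality, mirroring loci whose introns harbour several latent exons.
* **PE3** (139 nt by default): a weak decoy donor with the non-consensus A
  at +5, paired with an acceptor 139 nt upstream. The planted causal variant
  is the +5 A>G substitution 4629 bp into the intron; the generator verifies
  against the loaded donor model that the reference 9-mer scores below the
  activation threshold (10 by default) and the alternate 9-mer above it.

`simulate_pedigree_vcf()` adds a six-member pedigree (two unaffected
parents, four affected siblings — the sequenced core of a consanguineous
family; the full first-cousin loop is assumed but not genotyped, since the
real per-family structures are not published), dense biallelic markers
(2 kb spacing), background variants, and two planted autozygous segments of
80 kb and 60 kb shared by all affected siblings. Affected individuals are
homozygous for a founder haplotype across each segment and homozygous-alt
at the causal site; parents are heterozygous there. Background MAFs follow
Beta(0.2, 2) truncated to (0, 0.5], giving the realistic excess of rare
variants that makes frequency filters do non-trivial work. The causal
variant carries no MAF annotation — a variant absent from frequency
databases — which is why `filter_frequency` keeps unannotated records by
default.

All outputs are deterministic given a seed, and the VCF is the canonical
exchange format (written and re-read through `write_vcf`/`read_vcf`).

### What the toy scale does and does not show

Real autozygous segments in first-cousin offspring span megabases; on a
200 kb contig that is impossible, so lengths are scaled down once and for
all: ROH minimum length 50 kb with `min_markers = 10` at 2 kb marker
spacing (the 1 Mbp / 25-marker defaults of `detect_roh` remain the
real-data setting; the spacing is chosen so a planted 80 kb segment carries
about 40 markers, enough for a marker-count threshold to be meaningful).
Passing tests on this system demonstrate the correctness of the chain's
logic — filters, interval arithmetic, scoring, frame bookkeeping — not
performance on real genomes: linkage disequilibrium, genotyping error,
segmental duplications and population structure are all absent from the
generator.

## Algorithmic choices

**ROH detection** is a greedy run-scan, not an HMM: runs of homozygous
calls tolerate up to `max_het` heterozygous calls (default 1); when the
budget is exceeded the run closes at its last homozygous marker and the
scan restarts after the breaking heterozygote, so emitted runs never
overlap. Endpoints are the first/last homozygous markers, which makes
single-individual runs over-extend through chance homozygosity beyond a
true segment; the cross-sibling intersection (`intersect_hbd`, built on
IRanges) trims these extensions, which is why shared-HBD regions recover
planted segments with reciprocal overlap above 0.9 while single-individual
runs are held to a looser bound. A likelihood-based detector would be a
reasonable replacement; the run-scan was chosen because it is auditable and
every parameter is exposed.

**Pseudoexon length convention.** A candidate runs from the first exonic
base after the acceptor AG to the last exonic base before the donor GT, so
its length equals the acceptor-to-donor boundary distance, and "an acceptor
139 nt upstream of the donor" is the same statement as "a 139-nt
pseudoexon". Defaults bound the search at 500 bp with candidate lengths in
[25, 500] nt — generous around typical reported pseudoexons while keeping
the scan linear. Candidates are ranked by the unweighted sum of donor and
acceptor scores; the ranking input is a plain data.frame column, so other
combinations are trivial to apply downstream.

**Consequence annotation** translates from the canonical start codon
through the insertion with the standard nuclear codon table, stopping at
the first stop codon. Frame status follows from the inserted length modulo
3; the last canonical residue is the number of complete canonical codons
upstream of the first insertion point; novel residues are those translated
beyond it before the stop. NMD uses the 50-nt rule (PTC at least 50 nt
upstream of the final exon–exon junction; threshold exposed), and a
`no_orf` flag returns `NA` for reporter (minigene) contexts where NMD
prediction is meaningless because the construct has no genuine open reading
frame.

**PSI** is `inclusion / (inclusion + 2 * exclusion)` with inclusion the sum
of both flanking junctions' counts — the convention that motivates the
factor 2, since each inclusion molecule spans two junctions but each
skipping molecule only one. A zero denominator yields `NA` (no coverage is
not zero inclusion). Junction coordinates follow the STAR splice-junction
dialect (1-based first and last intronic base).

**ACMG combination** uses the point system: supporting 1, moderate 2,
strong 4, very strong 8 (benign evidence negative), banded as ≥10
pathogenic, 6–9 likely pathogenic, 0–5 uncertain, −6..−1 likely benign,
≤−7 benign. Strength suffixes (`_sup`, `_mod`, `_str`, `_vstr`) override a
code's default class. This single rule reproduces the printed category of
every row of the packaged cohort table, including a likely-pathogenic call
at 9 points and an uncertain call at 5 — combinations that the original
categorical combining rules do not express cleanly once modified strengths
are in play. The packaged gene-to-condition map (isolated OCA, HPS, CHS,
...) is a plain TSV and editable. Note the package only *combines*
evidence codes; it never assigns them from variant features.

**Percentages and sizes** are rounded half-up (15/28 → 54%, 5/28 → 18%,
5873254 bp → 5.87 Mbp), matching how such figures are conventionally
printed; R's default banker's rounding would differ on exact halves.

## Degenerate inputs and numerical details

* Strict inequalities in the filters follow the usual printed wording:
  MAF strictly below the cutoff, VAF strictly above.
* Missing MAF keeps a record (rare by implication), missing VAF keeps it
  too; both configurable. Missing genotypes drop a site in the segregation
  filter by default (`missing_policy = "ignore"` skips the individual
  instead).
* `find_partners` truncates (with a warning) a search window that runs past
  a contig end rather than erroring.
* PWM probability rows are validated to sum to 1 within 1e-9; k-mer tables
  are validated for completeness with the number of missing windows
  reported.
* Multiallelic sites: the simulator only emits biallelic records, and
  `read_vcf` documents that it does not decompose; decompose upstream
  (e.g. `bcftools norm`) before filtering real call sets.

## Worked example

```{r example, eval = FALSE}
ref  <- make_reference(seed = 1)
gset <- simulate_pedigree_vcf(ref, seed = 7)
res  <- run_discovery_pipeline(gset, ref$gene_model, ref$genome)
res$hbd        # two shared regions, one per contig
res$top        # the planted +5 A>G donor variant, 139-nt candidate

pe3 <- res$top
iso <- build_isoform(ref$genome, ref$gene_model,
                     data.frame(start = pe3$acceptor_pos,
                                end   = pe3$donor_pos))
rep <- annotate_consequence(iso, ref$gene_model)
rep$frame_status   # "frameshift" (139 %% 3 == 1)
predict_nmd(rep, iso)

j <- simulate_junctions(ref$gene_model,
                        c(canonical = 0.5, "+PE3" = 0.5),
                        depth = 1e5, seed = 3)
psi_for_pe(j, ref$gene_model, "PE3")$psi
```

Problem sizes used throughout the package's own checks: 20 simulated
pedigrees (200 background variants each, ~190 markers), junction depths of
1e5, and the 29-row packaged cohort table. At these sizes the complete
recovery experiment runs in well under a minute on a laptop.

## Known limitations

* The shipped PWMs are first-order models; they rank consensus-like sites
  correctly but do not reproduce published maximum-entropy score values,
  which require the published tables (loadable via the k-mer format).
* Consequence annotation is implemented for plus-strand gene models; the
  synthetic system and most single-gene analyses are representable in that
  orientation.
* No branch-point or splicing enhancer/silencer models, no deep-learning
  splice predictors, and no CNV handling.
* The segregation filter implements the recessive-homozygous model only —
  the configuration relevant to consanguineous pedigrees.
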