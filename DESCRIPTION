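Package: pexscan
Title: Pseudoexon Discovery and Variant Interpretation in Consanguineous Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying and interpreting deep-intronic
    splice-activating variants in autosomal recessive disease. Implements
    pedigree-aware variant filtering (population frequency, allele fraction,
    region and recessive segregation filters), run-of-homozygosity detection
    and shared homozygosity-by-descent mapping across affected relatives,
    position-weight-matrix and k-mer table splice-site scoring with ref/alt
    deltas, pseudoexon delineation from activated cryptic splice sites,
    transcript-level consequence annotation (reading frame, novel peptide,
    premature termination, nonsense-mediated decay, protein truncation),
    junction-based percent-spliced-in estimation, and point-based ACMG/AMP
    variant classification with cohort summarization. Includes a synthetic
    data generator that emulates a consanguineous pedigree segregating a
    recessive pseudoexon-activating variant inside a shared autozygous
    segment, for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
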