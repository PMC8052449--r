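Package: pccr
Title: Prediction and Characterization of Pairs of Conserved Complementary Regions in Pre-mRNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A k-mer seeded dynamic-programming search for long-range,
    nearly perfect complementary region pairs (panhandles) within
    pre-mRNAs, using a nearest-neighbor thermodynamic model, together
    with the annotation and statistical machinery needed to build and
    interrogate a genome-wide catalog: construction of conserved
    intronic regions from annotation and conservation tracks,
    resampling null models (random shift, random gene, re-wiring false
    discovery estimation), exon inclusion (PSI) statistics, odds-ratio
    association tests for editing sites, eCLIP peaks and transcript
    ends, population-polymorphism analyses, covariation E-value
    aggregation with Stockholm export, and a deterministic synthetic
    genome generator with planted ground-truth duplexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
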