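Package: radcapkit
Title: Target Capture of ddRAD Loci: Simulation, Catalogue Building,
    Variant Filtering and Cross-Species Population Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for double-digest RAD (ddRAD) loci enriched
    by in-solution target capture across closely related species. Covers probe
    template curation from RAD locus catalogues (greedy similarity clustering,
    paralog, low-complexity and mitochondrial screening, 120-mer probe tiling),
    capture read processing (quality trimming, k-mer contaminant screening,
    paired-end merging, dual-index demultiplexing), read mapping with PCR
    duplicate marking by fragment identity, assembly-based reference
    construction with on/off-target labelling, diploid genotype calling with
    hard site filters, museum-DNA deamination profiling and directional
    filtering, and population summaries (Weir-Cockerham Fst, MAF/missingness
    filters, LD pruning, PCA). Ships a synthetic multi-species ddRAD/capture
    experiment generator with known truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
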