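Package: wagoseq
Title: Classification and Target Calling for Argonaute-Bound Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of Argonaute immunoprecipitation small RNA-seq
    libraries in nematode germlines. Classifies 18-30 nt reads into nine
    annotation categories, calls small-RNA-enriched repeat loci
    ("WAGO-repeats") from normalized coverage tracks, calls high-confidence
    antisense mRNA targets by rpkm thresholding, and builds the comparative
    summaries used to study stage-dependent target plasticity: size and
    first-nucleotide profiles, metagene 5'-bias curves, Z-score matrices,
    PCA of libraries, and Venn overlaps. Includes a synthetic-data module
    that generates a small genome, annotations, and archetype-specific
    simulated IP libraries with ground truth, so the whole pipeline is
    testable end to end without external data.
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
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
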