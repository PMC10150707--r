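Package: hydroxyscan
Title: Reduced-Representation 5-Hydroxymethylcytosine Profiling and
    Differential Hydroxymethylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genome-wide 5-hydroxymethylcytosine (5hmC)
    quantification from reduced-representation hydroxymethylation
    profiling (RRHP) libraries. Enumerates assayable CCGG sites by
    in-silico MspI digestion, filters and places protected-site reads,
    annotates sites to genomic features and CpG-island landscapes,
    quantile-normalizes counts within cell types, computes log2-CPM
    values with a fitted mean-variance trend, performs paired and
    empirical-Bayes moderated t-tests, detects differentially
    hydroxymethylated regions with a sliding-window Fisher combined
    probability statistic, and clusters samples and sites by UPGMA on
    Pearson correlation dissimilarity. A synthetic-data generator
    produces genomes, RRHP reads and negative-binomial count matrices
    with planted effects so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
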