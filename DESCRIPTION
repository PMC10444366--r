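Package: giscreen
Title: Genetic-Interaction Scoring for Pooled CRISPR Dropout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of pooled CRISPR/Cas9 dropout screens run in two
    genotype contexts to score genetic interactions. Converts raw sgRNA
    read counts into depth-normalized per-guide fitness (log2 fold
    changes), removes intensity-dependent bias between contexts with a
    binned MA/loess normalization, scores guide- and gene-level genetic
    interactions with an empirical-Bayes moderated one-sample t-test and
    Benjamini-Hochberg correction, computes screen quality-control
    metrics (replicate Pearson correlation, essential-gene dropout
    AUC-ROC), and summarizes gene-level scores over gene sets with a
    z-score statistic. Includes a synthetic pooled-screen generator with
    known ground truth for end-to-end validation, and an exact-match
    FASTQ guide counter.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
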