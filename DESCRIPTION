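Package: cgiscan
Title: CpG Island Prediction by CpG Clustering and Sliding Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts CpG islands in genomic sequence by two paradigms and
    evaluates their putative function. The clustering detector groups CpG
    dinucleotides by inter-CpG distance and assigns each cluster a
    negative-binomial p-value under a geometric null, so that statistical
    significance replaces the conventional length threshold; the
    Takai-Jones-style detector scans fixed windows against GC content,
    observed/expected CpG ratio, minimum-CpG and length thresholds. A full
    evaluation battery accompanies the detectors: interval overlap statistics
    (mean coverage, overlap fraction, nesting, TSS specificity), sensitivity
    and lower-bound positive predictive value against gold-standard
    unmethylated regions, p-value/window-length calibration by matched set
    sizes, CpG-islet extraction, methylation-state classification of CpGs and
    islands from bisulfite amplicon or read data, within-island methylation
    heterogeneity, and promoter coexpression analysis. A synthetic-data module
    generates genomes with planted CpG-dense islands, methylation tracks and
    expression matrices with known truth, so the whole pipeline is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
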