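Package: tenet
Title: Tracing Enhancer Networks Using Epigenetic Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies tumor-specific and normal-specific distal enhancers
    from array DNA methylation (beta values), guards the calls against
    cell-type contamination using control methylation profiles, links
    enhancer activity to gene expression genome-wide with Welch z scores,
    permutation empirical p values and Wilcoxon rank-sum tests under
    Benjamini-Hochberg control, and summarizes the resulting enhancer
    networks: transcription-factor hub ranking, probe-to-gene distance
    profiles, per-sample binary link states with binary/Ward clustering,
    and ChIP-peak overlap enrichment. Includes a synthetic cohort
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
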