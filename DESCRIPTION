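Package: genecgh
Title: Gene-Centric Copy Number Variant Discovery from Two-Channel aCGH
Version: 0.1.0
Authors@R:
    person("genecgh", "developers", email = "genecgh@example.org",
           role = c("aut", "cre"))
Description: Detection of gene copy number variants (CNVs) from two-channel
    array comparative genomic hybridization (aCGH) in species that lack a
    contiguous reference genome. Probes are tiled within gene sequences and
    calls are made per gene by probe voting rather than by genomic
    segmentation. Includes probe quality and gene eligibility filters used
    at array-design time, MA-plot computation with robust LOESS dye-bias
    normalization, GC-wave and probe-composition corrections, false
    discovery rate calibration from self-self hybridizations, per-gene CNV
    and presence/absence calls, and pedigree-level summaries (frequency
    classes, sharing across families, Tukey HSD family comparisons and
    genetic-map distribution reports). A simulation module generates probe
    panels, full-sib families with Mendelian CNV inheritance, and synthetic
    two-channel intensities with dye bias, GC waves and noise, together
    with ground-truth copy numbers, so that the whole pipeline is testable
    without hybridization data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
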