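Package: clonesim
Title: Simulation of Tumor Clonal Evolution with Overlapping SNVs and CNVs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constrained random generation of tumor phylogenies and their
    cancer cell fraction (CCF) trajectories across longitudinal samples,
    simulation of single-nucleotide variants and overlapping copy number
    variants (deletions, duplications, copy-neutral LOH) with
    scenario-adjusted variant allele frequencies and log-normal read
    depths, lossless export/import of complete simulations, two evaluation
    metrics for subclonal reconstruction (variation of information for
    variant clusterings, discrete spectral distance for clonal trees), and
    a generator for a systematic 88-configuration benchmark corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
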