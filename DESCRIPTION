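Package: rdnacn
Title: Droplet Digital PCR Quantification of rDNA Copy Number and Screen Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Poisson quantification of duplexed droplet digital PCR (ddPCR)
    assays for measuring ribosomal DNA (rDNA) copy number per haploid genome
    in budding yeast, together with the plate-scale machinery needed to run a
    copy-number screen: a droplet-partition simulator with sub-sampling and
    partitioning noise, per-well occupancy and concentration estimates with
    confidence intervals, a confidence-interval-based technical-error model,
    wild-type-threshold hit categorisation, chromosome XII/XIII dosage-ratio
    aneuploidy flagging, and CSV readers/writers plus a small command-line
    interface for the pipeline's tabular formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
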