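Package: tadfusion
Title: Differential Contact Enrichment Analysis of TAD Boundary Deletions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how a genomic deletion reshapes chromatin
    architecture in capture Hi-C contact maps. Implements VC_SQRT matrix
    balancing, distance-decay expected profiles, structural-variant-aware
    liftover of binned contacts under a coordinate-only ("easy") and a
    distance-decay-rescaled ("balanced") model, subtraction maps, the
    differential contact-enrichment statistic D(k,f) with Z-score
    transformation and insulation-change calling, allele-specific expression
    scoring from hybrid-cross SNP coverage with pseudocount ratios and
    Mann-Whitney testing, and a synthetic capture Hi-C generator emulating a
    three-TAD locus with boundary deletions.
License: MIT
Encoding: UTF-8
Imports: stats, utils, tools, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
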