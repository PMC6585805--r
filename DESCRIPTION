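Package: kinomekin
Title: Kinetic Analysis and Activity Calling for Peptide-Array Kinome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved tyrosine-kinase peptide-array
    (kinome profiling) data. Estimates maximal phosphorylation velocity (Vmax)
    as the tangent of each intensity-time curve within fixed early, mid and
    late kinetic windows, aggregates technical replicates with zero-clipping,
    and produces on/off activity calls by comparing each peptide's mean Vmax
    minus a multiple of its replicate standard deviation against a linear
    background trend fitted to the lowest-ranked peptides. Includes paired
    area-under-curve comparison of two culture substrates with an exact
    Wilcoxon matched-pairs signed-rank test, overlap and kinetic-class
    summaries, peptide-to-gene mapping with hypergeometric gene-set
    enrichment, and a synthetic kinetic-data generator with known ground
    truth for validating sensitivity and specificity of the calling rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
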