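Package: samsa
Title: Metatranscriptome Annotation Aggregation, Depth Evaluation and
    Differential Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-annotation analysis of shotgun metatranscriptomes built
    around MG-RAST-style tab-delimited best-hit annotation downloads.
    Parses annotation files, separates rRNA from mRNA matches, aggregates
    per-read annotations into sorted abundance tables, rolls counts up by
    taxonomic rank, and merges samples into count matrices.  Provides a
    subsampling procedure to judge whether sequencing depth suffices for
    stable abundance estimates, evaluation tools for ribosomal-depletion
    bias, mRNA-versus-rRNA organism concordance and paired-end versus
    single-read annotation yield, a transparent negative-binomial Wald
    test for two-group differential abundance with Benjamini-Hochberg
    correction, and a synthetic-data generator with known ground truth so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods,
    MASS,
    withr,
    yaml,
    vegan,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
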