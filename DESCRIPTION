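Package: methylscreen
Title: Integrative Promoter-Methylation and Expression Screening for
    Silenced Candidate Tumor-Suppressor Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for an integrative epigenomic screen that ranks
    promoter-hypermethylated, transcriptionally silenced genes between a
    parental cell line and derivative lines. Computes Infinium-style
    beta-values from methylated/unmethylated probe intensities, assigns
    array probes to strand-aware promoter windows, contrasts per-gene
    methylation (delta-beta) against RPKM-based expression fold-changes,
    and classifies genes into hypermethylated/hypomethylated quadrants.
    Also includes clone bisulfite-sequencing methylation calling with a
    bisulfite-aware global aligner, Kaplan-Meier and log-rank survival
    comparison after a median split, and a synthetic-data generator with
    known ground truth for validating the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
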