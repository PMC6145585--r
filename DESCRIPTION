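Package: stripescan
Title: Binding-Site Prediction and Quantitative Stripe Expression
    Analysis for Blastoderm Enhancers
Version: 0.1.0
Authors@R:
    person("Stripescan", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing transcription-factor regulation of
    Drosophila blastoderm stripe enhancers. Builds PATSER-style log-odds
    weight matrices from count matrices, scans DNA for binding sites with
    exact score-distribution p-values, and designs binding-site knockout
    mutations that spare overlapping sites of other factors. Scores
    enhancers for binding-site enrichment against an accessible-chromatin
    background with integer-threshold sensitivity scans, and quantifies
    co-evolution of two factors' site content across enhancer orthologs.
    Quantifies stripe expression from cellular-resolution embryo
    pointclouds: strip line traces, stripe peak extraction,
    ventral-lateral peak differences, co-stain normalized levels and
    nonparametric genotype comparisons. A synthetic-data module generates
    sequences, ortholog families and embryo cohorts with known ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
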