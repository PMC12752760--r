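Package: neoPNS
Title: Predicted Neoantigenic Scoring of Germline TP53 Missense Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-variant MHC class I neoantigenicity metrics for
    germline TP53 missense variants from peptide-by-HLA-I binding-affinity
    predictions: the Minimal Affinity Score (MAS), HLA Count Score (HCS),
    World Coverage Score (WCS, a Hardy-Weinberg population-coverage
    estimate from HLA-I allele frequencies) and Amplitude Score (AMS),
    combined into a Predicted Neoantigenic Score (PNS, 0-3). Provides the
    downstream genotype-phenotype association battery for carrier cohorts
    (inverted Kaplan-Meier onset curves, global and pairwise log-rank
    tests, tumour-topology risk ratios with FDR control, onset-age
    comparisons, normality-gated correlation), patient-level HLA-I
    stratification, and a synthetic-data generator that emulates the
    statistical structure of Li-Fraumeni carrier registries so the whole
    pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    Biostrings,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Genetics, ImmunoOncology, Survival, Software
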