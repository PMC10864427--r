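Package: neoscreen
Title: Neoantigen Prioritization from Somatic Missense Variants with
    Structural and Assay-Level Validation Metrics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies and prioritizes candidate neoantigens from somatic
    missense variants. Enumerates all 8-12-mer mutant/wildtype peptide pairs
    covering a substituted residue, scores them against patient HLA class I
    alleles through a uniform binding-predictor interface (with a built-in
    deterministic predictor for offline use), applies a six-criterion filter
    (tumor DNA/RNA depth, variant allele fraction, FPKM expression, primary
    predictor IC50, consensus predictor vote, wildtype/mutant fold change)
    and ranks survivors by fold change (agretopicity). Companion modules
    compute structural validation metrics on peptide-HLA complexes (P2-P9
    anchor distance, inter-chain atom contacts, hydrogen bonds, MM/GBSA
    trajectory window averages) and assay-level summaries (percent cytotoxic
    lysis, mean +/- SEM, ANOVA with Tukey post hoc comparisons). A synthetic
    cohort generator with planted ground truth makes the full pipeline
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    VariantAnnotation,
    IRanges,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
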