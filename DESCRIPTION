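Package: gxcmap
Title: Context-Specific eQTL Mapping in Single Cells via Structured Linear Mixed Models
Version: 0.1.0
Authors@R: person("gxcmap", "developers", role = c("aut", "cre"),
    email = "gxcmap@example.org")
Description: Detects and characterizes genotype-by-context (GxC) interaction
    effects on single-cell gene expression. Implements a linear mixed model
    with a low-rank cellular-context covariance (Sigma = C C'), a
    relatedness-by-context (Hadamard product) term for the donor repeat
    structure of single-cell data, a variance-component score test for GxC
    with a mixture-of-chi-squares null, a likelihood-ratio association test,
    BLUP estimation of per-cell allelic effects, semi-synthetic Poisson count
    simulation, calibration and power benchmarking, and a two-stage
    association-then-interaction discovery workflow with gene-level
    Bonferroni and across-gene Storey FDR correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
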