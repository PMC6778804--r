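Package: skinflow
Title: Two-Layer Skin Transcriptome Modeling, Gene-Flow Classification and
    Enrichment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis of developmental two-layer (periderm and
    basal cell) skin transcriptomes profiled by bulk RNA-seq of sorted cell
    populations across timepoints. Fits per-gene, per-condition normal
    models on the log2 scale with variance partitioned into a technical
    component estimated from quantifier bootstrap samples and a biological
    component estimated from replicates with empirical-Bayes shrinkage
    toward a mean-variance trend. Classifies genes at each timepoint by
    fold-change-threshold ordering probabilities into skin/nonskin and
    periderm-/basal-preferred categories, concatenates the per-timepoint
    categories into cross-timepoint "flows", tests gene sets for
    hypergeometric enrichment over flows, ranks genes by skin enrichment
    plus layer specificity, and clusters experiments by principal
    components with complete-linkage Chebyshev hierarchical clustering and
    optimal leaf ordering. Includes a synthetic-data generator emulating
    the 12-condition, 23-sample sorted-cell design with multinomial
    bootstrap count tensors, so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    mvtnorm,
    rhdf5,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite
Config/testthat/edition: 3
biocViews: RNASeq, GeneExpression, DifferentialExpression, Clustering,
    GeneSetEnrichment
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
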