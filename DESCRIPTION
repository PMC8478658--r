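Package: amlmetab
Title: Integrated Genomic-Metabolomic Classification of Acute Myeloid Leukemia
Version: 0.1.0
Authors@R: person("AML", "Metabolomics Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for integrated genomic and metabolomic analysis of acute
    myeloid leukemia (AML) cohorts. Implements dual-biofluid (serum and urine)
    NMR spectral preprocessing, latent-variable modelling (PCA, PLS-DA,
    sparse PLS-DA) with stochastic grid search and stratified cross-validated
    classification; intracellular mass-spectrometry metabolomics statistics
    (DNA normalization, differential analysis with fold-change and FDR
    filters, random-forest assessment, pathway over-representation, outlier
    calling); genomic-guided latent-component selection and biofluid
    integration with hierarchical clustering and cluster-genotype association
    tests; and constraint-based metabolic network analysis (gene-protein-
    reaction rules, expression-derived constraints, flux variability
    analysis, metabolite production/consumption capability, perturbation
    networks). A seeded synthetic-cohort generator provides spectra, cell
    metabolomes, expression tables and toy SBML models with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
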