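Package: gcsem
Title: Structural Equation Modelling of Genome-Wide Genetic Covariance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood structural equation modelling of genetic and
    residual covariance across multiple phenotypes in unrelated individuals,
    using a genetic relationship matrix (GRM) estimated from genome-wide
    genotypes. Implements saturated (Cholesky), independent pathway, hybrid
    independent-pathway/Cholesky (IPC) and bi-factor model families with
    Wald tests and Delta-method standard errors for standardized loadings,
    SNP heritabilities, genetic correlations and factorial co-heritabilities.
    Includes a data-driven factor-discovery pipeline (genetic PCA, weighted
    genetic exploratory factor analysis, constrained hybrid models, fit
    comparison), univariate and bivariate GREML variance-component
    estimation, GCTA-format GRM input/output, phenotype transformation
    utilities (deviance residuals, two-stage rank normalisation) and a
    simulation harness reporting bias, empirical SE, coverage and their
    Monte-Carlo SEs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
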