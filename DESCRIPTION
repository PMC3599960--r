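Package: somportraits
Title: Self-Organizing Map Expression Portraits with Differential
    Expression and Gene Set Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains a linearly initialized self-organizing map (SOM) on
    gene-centered log10 expression profiles and renders sample-specific
    metagene portraits. Detects over- and underexpression spots by a
    quantile criterion, ranks genes with fold-change, weighted average
    difference (WAD) and shrinkage-t scores built on locally pooled error
    estimates, estimates local and tail-area false discovery rates with a
    Grenander-type density estimator, compares alternative ranked gene
    lists (CAT, p-CAT, rank correspondence), and assesses gene-set
    overrepresentation (hypergeometric) and enrichment (regularized GSZ
    score) at global, spot and metagene resolution. Includes a seeded
    synthetic-data generator with planted co-expression modules for
    end-to-end validation, and a pipeline driver that writes a full
    report directory of images and tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    limma,
    pheatmap,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
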