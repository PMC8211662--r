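Package: embryoaxis
Title: Lineage Annotation, Reference Projection and 3D Angular Asymmetry
    Analysis for Post-Implantation Embryo Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-cell RNA-seq and 3D imaging data from
    early post-implantation embryos. Provides quality-control filters
    (mitochondrial fraction, detected genes) and embryo inclusion rules,
    marker-signature lineage annotation with one-vs-rest marker ranking,
    reference projection of query cells by L2-regularised multinomial
    logistic regression with quantitative match scores, AUCell-style regulon
    activity scoring, rank-based co-expression screens of secreted pathway
    antagonists with Benjamini-Hochberg correction, nonparametric
    treatment-group statistics (Kruskal-Wallis with Dunn's post hoc), and a
    3D angular-asymmetry pipeline that maps marker-positive hypoblast cells
    onto a 0-180 degree hemispheric coordinate and tests for localisation
    bias by label permutation. A synthetic-embryo generator (negative
    binomial counts, hemispherical geometries with von Mises-Fisher-style
    marker concentration) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
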