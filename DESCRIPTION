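Package: rhizotype
Title: Discovery and Validation of Characteristic Rhizosphere Bacteria from
    Genus Abundance Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for discovering the bacterial genera that
    distinguish groups of plant rhizosphere soil communities and for tracing
    their downstream effect on soil nutrients and crop quality. Starting from
    a genus-level abundance table the package profiles alpha and beta
    diversity (Shannon, Simpson, Chao1, rarefaction and accumulation curves,
    Bray-Curtis dissimilarity), partitions samples by K-means, screens key
    differential genera with an orthogonal partial least squares discriminant
    analysis (OPLS-DA) model validated by permutation testing and scored by
    variable importance in projection (VIP), validates candidate genus sets
    with a five-classifier repeated stratified holdout harness (KNN, RBF-SVM,
    single-hidden-layer neural network, random forest, gradient boosting)
    pooled into overall confusion matrices and ROC curves, selects
    characteristic genera as the intersection of the random-forest and
    boosting importance rankings, and links taxa, soil available N/P/K and
    leaf quality indexes by redundancy analysis, correlation networks and PLS
    path modelling. A Dirichlet-multinomial simulator generates abundance
    tables with planted differential genera and chained nutrient and quality
    phenotypes so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    cluster,
    class,
    e1071,
    nnet,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
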