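Package: kpcaInterp
Title: Interpretable Kernel PCA with Direct-Sum Data Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kernel principal component analysis for single and fused
    multi-block datasets, with tools that restore the interpretability
    classical biplots offer. Samples are embedded by solving the centered
    dual eigenproblem on the Gram matrix; heterogeneous blocks (for
    example liver gene expression and hepatic fatty-acid concentrations)
    are fused through direct-sum kernels; input variables and linear
    combinations of variables are rendered as per-sample tangent vectors
    giving the local direction of maximum growth in the embedding; and a
    cosine-averaging correlation statistic ranks variables against any
    reference direction, such as the vector joining two cluster
    centroids. Seeded generators for a three-group toy configuration and
    a balanced two-factor, two-block study design support testing without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    yaml,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
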