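Package: bulkpurity
Title: Tumor Purity Estimation from Bulk RNA-Seq Trained on Simulated Pseudobulks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tumor purity (malignant-cell fraction) of bulk RNA-seq
    samples with a small feed-forward regression network trained on pseudobulk
    tumors simulated on the fly from an annotated single-cell corpus. Provides
    CPM/TPM normalization and the model-input transform, cross-modality gene
    selection combining a CPM prevalence filter with a two-sample
    Kolmogorov-Smirnov screen, within-sample pseudobulk simulation at known
    purity, L1-trained multilayer-perceptron regression with sliding-window
    early stopping, guarded inference with missing-gene warnings, evaluation
    metrics (MAE, RMSE, Pearson, concordance correlation), and a fully
    synthetic single-cell/bulk fixture generator so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    optparse,
    tibble,
    dplyr,
    tidyr,
    readr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
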