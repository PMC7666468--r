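Package: methprog
Title: Methylation-Based Prognostic Classification for Non-Metastatic
    Clear Cell Renal Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving prognostic risk classifiers for non-metastatic
    clear cell renal cell carcinoma from genome-wide DNA methylation array data
    and clinicopathological variables. Implements Directed Cluster Analysis
    (DCA): per-CpG binarization by exact one-dimensional 2-means, minority-
    fraction and mean-separation prefilters, k-means clustering of binary
    profiles, and per-cluster consensus methylation variables. Provides probe
    filtering for 450K-style arrays, differential-methylation calling against
    tumor-free reference tissue, the Mayo (Leibovich) progression score,
    principal-component logistic-regression classifiers evaluated at a fixed
    sensitivity, agreement and survival analyses (Cohen's kappa, ROC/AUC with
    DeLong comparison, Kaplan-Meier cumulative incidence, log-rank), and a
    seeded synthetic-cohort generator with planted cluster structure for
    end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
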