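Package: cereconn
Title: Task-fMRI Network Dysconnectivity, Familial Contrasts and
    Clinical-Cognitive Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for multiscale graph analysis of task-based
    functional MRI in the schizophrenia spectrum. Builds sparse weighted
    functional-connectivity graphs from ROI time series (Pearson correlation,
    Fisher r-to-z, percentile thresholding), computes nodal and network-level
    metrics (strength, Onnela weighted clustering, inter-/intra-network
    connectivity, network degree), runs the familial contrast framework
    (Welch t, Cohen's d, Benjamini-Hochberg FDR), evaluates effect-size
    weighted composite biomarkers by ROC/AUC/Youden analysis, and stratifies
    clinical-cognitive profiles into subtypes by PAM consensus clustering
    with PAC, adjusted Rand, Jaccard, silhouette and Calinski-Harabasz
    stability metrics and permutation testing. A seeded synthetic-cohort
    generator emulates the four-group (patients, siblings, controls, control
    siblings) N-back study design so every stage is testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
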