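Package: labscan
Title: Quality Control and Lab-Wide Association Scans for EHR Laboratory Values
Version: 0.1.0
Authors@R: person("labscan", "maintainers", email = "labscan@example.org",
    role = c("aut", "cre"))
Description: Cleans raw long-format electronic health record (EHR) laboratory
    observations into analysis-ready per-patient median values with a
    rank-based inverse normal transformation, and runs lab-wide association
    scans (LabWAS): per-lab linear models of transformed lab values on a
    standardized predictor (e.g., a polygenic score) adjusted for sex,
    restricted cubic splines of median EHR age, and principal components,
    with Bonferroni control across the scan family. Includes a synthetic
    EHR generator with a ground-truth ledger so the whole pipeline can be
    exercised and validated without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
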