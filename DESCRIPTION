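Package: ppiwfd
Title: Protein-Protein Interaction Site Prediction with Distance-Weighted
    Feature Descriptors and Bagging
Version: 0.1.0
Authors@R:
    person("ppiwfd", "maintainers", email = "ppiwfd@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interaction (interface) residues from
    complex structures and sequence profiles. Computes per-residue
    solvent-accessible surface area (Shrake-Rupley) in the bound and unbound
    states, relative accessibility, depth and protrusion indices, and combines
    them with HSSP-style sequence-profile statistics and physicochemical
    scales into a 50-dimensional residue descriptor. A sliding window of
    neighbour descriptors, each divided by its C-alpha Euclidean distance to
    the query residue, forms the weighted feature descriptor (WFD) used to
    train a bagging ensemble of classification trees. Includes surface and
    interface labeling rules based on buried surface area, evaluation metrics
    (accuracy, precision, recall, F-measure, MCC, ROC/AUC), and a synthetic
    complex and dataset generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
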