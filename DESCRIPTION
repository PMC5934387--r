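Package: modulebayes
Title: Eigengene-Based Bayesian Network Classification of Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects coexpression modules in gene-expression matrices via a
    weighted correlation network (soft-thresholded adjacency, topological
    overlap, average-linkage clustering), summarizes each module by its
    eigengene (first principal component on class-balanced data), learns an
    ensemble of consensus discrete Bayesian networks over the eigengenes plus
    a binary disease ('Effect') node, and predicts disease class for new
    samples by majority vote, including samples profiled on a different
    expression platform, via rank-preserving eigengene projection. Includes
    probe-level preprocessing (moderated t ranking, top-fraction filtering,
    probe-to-gene collapsing), Hartemink mutual-information discretization,
    BDe structure scoring with hill climbing and bootstrap model averaging,
    likelihood-weighting inference, performance reporting, and a synthetic
    data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
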