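Package: iqrank
Title: Pairwise-Comparison Ranking and Agreement Statistics for
    Subjective Image-Quality Observer Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design, run and evaluate subjective image-quality
    observer studies that replace Likert scoring with a
    comparison-minimizing pairwise-comparison ranking protocol. Implements
    the Ford-Johnson (merge-insertion) sorting algorithm as an interactive,
    resumable comparison session; two-way random-effects absolute-agreement
    intraclass correlation coefficients (single and average measures) with
    F-based 95% confidence intervals; Thurstonian synthetic observers and
    scan-pool generators so complete study designs can be exercised without
    any imaging data; and the tabular and graphical agreement diagnostics
    (rank-spread boxplots, confusion matrices, repeated-rank plots) such
    studies report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
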