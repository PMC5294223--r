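Package: tdminfer
Title: Directed Gene Regulatory Network Inference from Time-Series
    Expression via Time-Delayed Mutual Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from time-series
    gene expression data with an information-theoretic pipeline: per-gene
    detection of the first substantial change of expression (ScE) against
    a ratio threshold, orientation of gene pairs by which gene changes
    first, time-delayed mutual information maximised over a small lag
    window, and an influence threshold that decides edge presence.  The
    three inference steps can be partitioned between "mapper" and
    "reducer" roles in four equivalent ways (M0-M3) and executed on a
    local parallel worker pool.  Includes readers for DREAM4-style
    time-series files and gold-standard edge lists, a network scorer with
    the significance tests used to justify parameter defaults, a
    synthetic benchmark generator with known ground truth, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    parallel,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
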