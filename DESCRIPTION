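Package: svcluster
Title: Structural Variant Clusters from Multi-Study Variant Submissions
Version: 0.1.0
Authors@R:
    person("SVC", "Maintainers", email = "svc@example.org", role = c("aut", "cre"))
Description: Computes structural variant clusters (SVCs): a non-redundant set
    of disjoint genomic regions obtained by partitioning submitted structural
    variant (SSV) placements at every breakpoint, with each region carrying
    the number of SSVs that contain it (its concordance count). Includes
    readers for dbVar-style tab-delimited study files with fuzzy
    (outer/inner) coordinates, a genome-ordered multi-study merge, GVF /
    bedGraph / WIG / BED exporters, filtering and rare-vs-common
    classification, comparison of user intervals against SVC sets,
    feature-file annotation, summary statistics, a deterministic
    synthetic-data generator with a brute-force per-base oracle, and a
    subcommand-style command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
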