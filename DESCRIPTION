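Package: monet
Title: Drug Mode-of-Action Networks from Replicate Treatment Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds drug mode-of-action (MoA) networks from replicate
    compound-treatment expression profiles, in the style of connectivity-map
    analyses of breast cancer cell lines. Provides the preprocessing chain
    from background-adjusted probe intensities to per-treatment log2
    fold-change profiles (quantile normalization, rank-invariant
    normalization against a vehicle baseline, median-polish summarization),
    per-drug signature gene-set selection with a replicate-consistency
    statistic and an empirically sampled null, quality-control filtering of
    outlier replicate samples, a signature-based drug-drug distance with
    empirically calibrated clustering into MoAs, MoA network construction
    with betweenness-centrality centers, and similar/reverse ranking of MoAs
    and drugs against a query expression profile. A synthetic-data generator
    with planted MoA structure supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    withr
Config/testthat/edition: 3
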