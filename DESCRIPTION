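Package: bloomloci
Title: Polysaccharide Utilization Locus Detection and CAZyme Profiling in
    Bloom Metagenome Time Series
Version: 0.1.0
Authors@R:
    person("bloomloci", "developers", email = "bloomloci@example.org",
           role = c("aut", "cre"))
Description: Post-annotation analysis toolkit for merged-assembly metagenomic
    time series of phytoplankton blooms. Provides consensus filtering of
    carbohydrate-active enzyme (CAZyme) annotations against PFAM/KEGG/COG
    co-annotations, per-taxon function copy numbers normalized by the median
    coverage of universal single-copy genes, chi-squared distances and
    classical multidimensional scaling of CAZyme family profiles, Spearman
    screening of copy numbers against chlorophyll a with Benjamini-Hochberg
    false discovery rate control, and rule-based detection of polysaccharide
    utilization loci (susC-susD tandems extended by strand and intergenic-gap
    rules). A synthetic community generator with a ground-truth manifest makes
    the whole pipeline testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
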