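Package: eigenlipid
Title: Eigenlipid Co-Occurrence Analysis of Ocean Lipidomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Weighted correlation network analysis of depth-resolved marine
    lipidomes. From a lipid feature table and oceanographic sample metadata
    the package removes contaminant features by blank comparison, applies a
    centered log-ratio transform, detects co-occurring lipid clusters
    ("eigenlipids") by soft-thresholded topological-overlap clustering,
    projects clusters into held-out ocean regions and scores their
    reproducibility with an in-group proportion permutation test. Downstream
    analyses characterise the clusters' vertical and biogeographic structure
    (depth of maximum intensity, deep chlorophyll maximum, Longhurst province
    enrichment), integrate distributional, geographic and depth views into a
    meta-dendrogram with Monte Carlo node significance, compare structural
    and distributional clusterings by tanglegram entanglement, and quantify
    environmental drivers of lipid remodelling (chain length versus
    temperature, random-forest attribution of temperature and phosphate with
    individual conditional expectation curves, PUFA layer contrasts). A
    seeded synthetic-ocean generator with planted ground truth supports
    benchmarking and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ape,
    lme4,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
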