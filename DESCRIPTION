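Package: arcomics
Title: Circular Genome Plots of Omics Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses genome-wide association edge lists (delimited text and an
    extended Simple Interaction Format dialect), resolves heterogeneous node
    labels (gene symbols, ENSEMBL/ENTREZ identifiers, chr:start:end positions)
    to genomic coordinates against built-in, custom or composite multi-organism
    references, filters edges by weight or gene-label sets, bundles dense edge
    sets into genomic windows, and renders filterable circular genome plots as
    reproducible SVG together with grid (TSV/HTML) and network (SIF) exports.
    Ships a ten-organism reference catalog, annotation-ring tracks (bar,
    histogram, heatmap), seeded synthetic fixture generators, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
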