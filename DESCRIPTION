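Package: narweb
Title: Network-Area Relationships for Trophic Metawebs on Gridded Ranges
Version: 0.1.0
Authors@R: person("narweb", "developers", role = c("aut", "cre"),
    email = "narweb@example.org")
Description: Builds species-area and network-area relationships (SARs and
    NARs) from a trophic metaweb and gridded species presence/absence.
    Local food webs are induced from the metaweb on the species co-occurring
    in spatially coherent cell aggregations produced by a spiral traversal;
    network properties (links, generality, vulnerability, trophic-level
    fractions, consumers' diet overlap) are tracked across areas and
    summarised by power-law exponents fitted with damped nonlinear least
    squares. Includes richness-matched null models (metaweb-subsampled and
    uniformly random networks), per-region environmental predictors
    (Bray-Curtis habitat dissimilarity, Moran's I habitat clustering,
    climate summaries), commonality analysis for variance partitioning, and
    a synthetic-data generator (niche-model metaweb, contiguous
    autocorrelated ranges, clustered habitat mosaics, climate fields,
    contiguous region partitions) so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    igraph,
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
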