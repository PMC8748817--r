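Package: commtrait
Title: Community-Aggregated rrn Copy Number, Biosphere Classification, and
    RMT-Thresholded Co-Occurrence Networks for Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trait-based analysis of microbial community abundance structure.
    Partitions OTUs into abundant, intermediate and rare biospheres from
    relative abundance and occurrence thresholds; assigns ribosomal RNA operon
    (rrn) copy numbers to OTUs by hierarchical taxonomic matching against an
    rrnDB-style trait table and computes the abundance-weighted community-level
    rrn copy number; provides weighted mean pairwise phylogenetic distance,
    normalized weighted UniFrac, Pearson trait-nutrient correlation and
    permutation-based partial Mantel tests; infers signed Spearman
    co-occurrence networks with a random-matrix-theory threshold scan,
    fast-greedy modules, degree-preserving null models and link-sign summaries;
    and generates synthetic communities with planted ground truth (lognormal
    species-abundance distributions, trait-nutrient coupling, Gaussian-copula
    signed associations) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
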