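Package: somase
Title: Self-Organizing Maps for Allele-Specific Expression Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs missing allele-specific expression (ASE) signals in
    corrupted diploid individuals with a two-phase procedure: a batch-trained
    self-organizing map (SOM) on a hexagonal lattice assigns each corrupted
    expression profile to a cluster, and a cluster-conditional completion rule
    based on allele-pair frequencies and conditional mean read counts fills in
    the missing alleles and their expression levels. Also provides per-allele
    relevance indices (local error contribution and discriminative index) with
    Z-score selection of anomalous alleles and genes, clustering validity
    indices (SQI, Fowlkes-Mallows, normalized mutual information, Rand),
    a Jaccard-graph spectral embedding with Nystrom out-of-sample extension,
    and synthetic population generators (signature-based artificial
    populations, Hardy-Weinberg evolutionary expansion, and sequential Monte
    Carlo augmentation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    igraph,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
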