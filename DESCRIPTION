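Package: delimatch
Title: Single-Locus Species Delimitation Engines and Partition Congruence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: De novo species delimitation from aligned DNA barcode data
    (fixed-threshold single-linkage clustering, statistical-parsimony
    networks, automatic barcode-gap discovery, ranked hierarchical
    partitioning, and Poisson tree processes maximum-likelihood
    delimitation), together with the taxonomic match ratio for comparing
    molecular operational taxonomic units against morphospecies,
    split/lump classification of reference species, pairwise
    method-similarity matrices, and principal coordinate ordination of
    delimitation methods. Includes a seeded simulator of barcode
    communities with known species boundaries and controllable
    discordance (introgression, recent divergence, geographic
    substructure) so every stage of the pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    phangorn,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
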