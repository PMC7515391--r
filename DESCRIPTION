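Package: piclink
Title: Link Prediction with the Potential Information Capacity Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Similarity-index link prediction for undirected simple networks
    (protein-protein interaction, neural, ecological, social). Implements the
    potential information capacity (PIC) index, a Cannikin-Law-motivated score
    in which every neighbor of an endpoint acts as an information channel whose
    capacity is set by the number of two-hop paths and the weakest path's
    transfer rate, together with nine classical baselines (common neighbors,
    resource allocation, Adamic-Adar, CAR, preferential attachment, local path,
    Katz, average commute time and cosine similarity on the Laplacian
    pseudoinverse). Provides edge-list and GraphML input, train/probe edge
    splitting, AUC and precision-at-L evaluation with multi-realization
    averaging and parameter sweeps, a Barabasi-Albert synthetic-network
    generator, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
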