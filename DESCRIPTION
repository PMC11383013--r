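Package: chanet
Title: Connectivity Hyperalignment and Brain Network Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline studying how connectivity hyperalignment (CHA)
    changes estimated functional brain network topology across spatial scales.
    Builds per-subject connectomes against parcel-averaged connectivity targets,
    derives ROI-wise and searchlight-wise orthogonal Procrustes mappers into a
    shared functional space, quantifies alignment by inter-subject correlation
    of connectivity profiles, computes global and local graph metrics on
    density-thresholded networks at coarse (region) and fine (vertex) scales,
    detects multi-subject community structure by multilayer modularity with
    categorical interlayer coupling (allegiance, recruitment, integration), and
    predicts an individual trait from topological feature patterns with ridge
    regression validated across held-out runs. Includes a synthetic multi-subject
    cohort generator with known ground truth (local orthogonal misalignment,
    planted modules, trait-coupled fine-scale topology).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
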