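Package: cmomo
Title: Constrained Multi-Objective Molecular Optimization in Latent Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage constrained multi-objective evolutionary optimization
    of small molecules in a continuous latent space. Molecules are embedded
    by a pluggable encoder-decoder, varied by a blended linear crossover and
    a fragmentation-based mutation operator, and selected first by NSGA-II
    environmental selection (unconstrained stage) and then by a ranking
    aggregation scheme that blends a property-preference ranking with a
    constraint-preference ranking under a cosine-decayed weight. Drug-likeness
    constraints (ring sizes restricted to five or six atoms, absence of
    structural-alert substructures) enter through per-constraint violation
    degrees aggregated with max-normalization over the selection population.
    Includes success-rate and hypervolume metrics, an analytic test problem
    with a known constrained Pareto front, and a deterministic table codec
    plus a packaged toy molecule world for end-to-end testing without
    pretrained autoencoder weights. Primitive molecular descriptors (QED,
    Crippen logP, synthetic accessibility, fingerprints, ring perception,
    SMARTS matching) are computed through a bundled RDKit helper script run
    with the system Python.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
SystemRequirements: Python (>= 3.8) with RDKit available as 'python' on PATH
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
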