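Package: fflscape
Title: Function Landscape, Plasticity and Evolvability of Feed-Forward
    Loop Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the dynamical response of the eight feed-forward
    loop (FFL) motif topologies with a two-equation gene-regulation model,
    classifies responses into six qualitative classes (graders and
    pulsers), estimates per-motif function-probability distributions by
    Monte-Carlo parameter sampling, and derives distribution-shape
    statistics (sample kurtosis, Shannon entropy), plasticity and
    predicted motif abundance. Implements an in-silico mutation protocol
    (single and accumulated parameter mutations) yielding
    class-transition matrices, mutational robustness and evolvability,
    and correlates the derived scores with motif-abundance vectors.
    Reference probability and transition tables are packaged as
    machine-readable fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
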