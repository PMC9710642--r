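Package: glvsim
Title: Synthetic Longitudinal Microbiome Data from Generalized Lotka-Volterra Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic longitudinal relative-abundance read-count
    data from noisy generalized Lotka-Volterra (gLV) dynamics over one or
    more interacting "nodes" (data types or ecosystems). Supports random
    community interaction matrices with tunable connectivity and
    self-limitation, multi-individual cohorts with shared dynamics and
    resampled initial conditions, case-control splits driven by always-on
    random-response interventions, ridge-regression recovery of gLV
    parameters from abundance timecourses, realism summaries (alpha
    diversity, sparsity, differential abundance), stacked-bar and PCA
    trajectory visualization, and a command-line front end for
    reproducible power-analysis sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    optparse,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
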