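Package: mvdsgrappa
Title: Multiple Variable Density Sampling and GRAPPA/NL-GRAPPA
    Reconstruction for Parallel MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for line-based Cartesian undersampling design and
    k-space reconstruction in parallel magnetic resonance imaging.
    Builds traditional uniform, variable density (VDS) and multiple
    variable density (MVDS) phase-encode sampling masks with exact line
    budgets and net reduction factors; reconstructs missing k-space
    lines per outer-reduction-factor region with GRAPPA and with the
    explicit second-order polynomial feature expansion of NL-GRAPPA;
    simulates multi-coil acquisitions from analytic phantoms and smooth
    or spatial-harmonic coil sensitivities; and scores reconstructions
    with sum-of-squares coil combination, artifact power and SNR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
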