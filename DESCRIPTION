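Package: ecglognorm
Title: Sigma-Lognormal Decomposition of the ECG PQRST Complex
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models each ECG PQRST complex as a sum of six time-shifted,
    scaled lognormal components (P, Q, R, S, and a T wave built from a
    positive and a negative lognormal), constrained by a hand-fitted
    prototype and per-parameter box bounds. Provides the forward model and
    its closed-form parameter-box envelopes, beat detection and
    duration-normalized epoching with SNR-based quality control, an
    episodic fitting environment with a peak-order constraint (suitable
    for policy-search optimizers) together with a deterministic baseline
    optimizer, a synthetic single-lead infant ECG generator with known
    ground truth, and a downstream parameter-versus-age correlation stage
    with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
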