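Package: vocalid
Title: Vocal Identity Ontogeny Analysis for Animal Calls
Version: 0.1.0
Authors@R:
    person("Haidlhof", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying individual vocal signatures in developing
    animals and how they change with age and behavioural context. Provides a
    seeded synthetic call-dataset generator with known individual signatures,
    amplitude-envelope call segmentation and extraction of eight spectral and
    temporal descriptors from WAV audio, permuted discriminant function
    analysis (pDFA) with a blocking (restriction) factor, the potential of
    identity coding (PIC) statistic with age-trend models, Kaiser-Meyer-Olkin
    factorability screening, and dyadic acoustic dissimilarity ontogeny based
    on per-individual daily median profiles. An end-to-end pipeline and a
    command-line interface orchestrate the full analysis and write
    consolidated CSV/JSON reports.
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
    optparse
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
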