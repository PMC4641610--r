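Package: heliplex
Title: Triplex Real-Time PCR Species Diagnostics for Helicoverpa armigera and H. zea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for a hydrolysis-probe (TaqMan-style) triplex
    real-time PCR assay that separates the Old World bollworm (Helicoverpa
    armigera) from the corn earworm (H. zea) using two ITS2 probes and an 18S
    rDNA control probe. Provides IUPAC-aware oligonucleotide handling with
    salt-adjusted melting temperatures, in-silico PCR and probe-binding
    prediction on template sequences, quantification-cycle (Cq) calling from
    raw fluorescence traces with baseline subtraction and single-threshold
    crossing, the four-rule diagnostic decision tree with an auditable rule
    trace, dilution-series standard-curve fitting, and a seeded synthetic plate
    generator so the whole pipeline can be exercised and validated without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    ggplot2,
    jsonlite,
    methods,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
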