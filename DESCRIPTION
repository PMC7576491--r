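Package: pahrisk
Title: PAH Exposure Metrics, Source Diagnostics and Probabilistic Cancer
    Risk for Children in Coal-Heated Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing children's inhalation exposure to
    PM2.5-bound polycyclic aromatic hydrocarbons (PAHs) and the resulting
    incremental lifetime cancer risk (ILCR). Provides a configurable
    registry of the priority PAH congeners with benzo[a]pyrene toxic
    equivalency factors (TEFs), readers and validators for sample-level
    concentration and participant tables, BaP-equivalent exposure metrics
    with seasonal summaries and indoor/outdoor ratio classification,
    isomer diagnostic-ratio source attribution, deterministic dosimetry
    (inhalation rate from spirometry, lifetime average daily dose, ILCR),
    Monte Carlo uncertainty propagation with lognormal/truncated-normal
    parameter distributions and Kolmogorov-Smirnov distribution selection,
    and a synthetic-cohort generator that reproduces the statistical
    structure of seasonal personal and fixed-site measurements for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
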