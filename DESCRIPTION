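Package: bsapkit
Title: Buffer-Aware Aggregation-Propensity and Excipient-Adsorption Analysis
    for Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies excipient (buffer) adsorption on protein surfaces from
    molecular-dynamics trajectories and its effect on aggregation propensity.
    Implements the Spatial Aggregation Propensity (SAP) index and its
    buffer-aware extension (BSAP), a contact-based Buffer Adsorption Index
    (BAI), excipient-affinity interaction scores, residence-time and
    survival-probability analysis with double stretched-exponential desorption
    fits, Shrake-Rupley solvent-accessible surface areas, and supporting
    structural observables (radius of gyration, domain angles,
    surface-referenced radial distribution functions, Green-Kubo viscosity,
    Henderson-Hasselbalch buffer composition). Ships deterministic synthetic
    fixture generators so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
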