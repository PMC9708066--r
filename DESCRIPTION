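Package: thermosort
Title: Thermal Performance Curves, Phylogenetic Signal and Species Sorting
    for Microbial Isolates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives microbial physiological traits (carbon biomass,
    mass-specific growth rate, biomass-specific respiration rate, ATP
    content) from raw growth-respiration assay measurements, fits the
    four-parameter Sharpe-Schoolfield thermal performance curve with an
    explicit peak temperature to temperature-rate data to obtain thermal
    optima, peak rates and operational niche widths, quantifies
    phylogenetic signal of thermal optima (Pagel's lambda with a
    likelihood-ratio test, Blomberg's K with a permutation test) and
    reconstructs ancestral states under Brownian motion, and runs
    community-level trait statistics (sorting-temperature regression
    comparison, trait PCA, ATP-respiration power-law scaling, rank-sum
    phylum contrasts).  Includes a synthetic-data generator that emulates
    the full assay-to-community data flow with known ground truth for
    estimator calibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
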