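Package: phytoflux
Title: Compartmentalized Constraint-Based Modeling of Plant Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, curating and interrogating compartmentalized
    stoichiometric models of plant metabolism. Provides flux balance analysis
    (FBA) and parsimonious FBA on models with explicit cytosol, mitochondrion,
    plastid, peroxisome and vacuole compartments; a curation battery covering
    energy-generating-cycle detection, respiratory P/O ratio checks, weighted
    parsimonious gap-filling, reduction-degree yield bounds and biomass
    molecular-weight rescaling; E-Flux integration of replicate FPKM
    transcriptome tables and free amino-acid measurements; and paired
    soil-grown versus in-vitro condition simulation with pathway-level flux
    comparison. Ships a deterministic generator for a synthetic photosynthetic
    toy model (photosystems, cyclic and linear electron flow, Calvin cycle,
    glycolysis, TCA cycle, proton-explicit respiratory chain, GS/GOGAT
    nitrogen assimilation) together with matched synthetic expression and
    amino-acid data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
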