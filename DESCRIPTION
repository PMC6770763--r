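Package: pdl1net
Title: Kinetic Network Modeling of PD-L1 Regulation in Neuroblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation modeling of the receptor kinase
    signaling network that controls PD-L1 (CD274) transcription in
    neuroblastoma. Provides S4 classes for compartmentalized reaction
    networks with mass-action, Henri-Michaelis-Menten and modified
    (modifier-proportional) Henri-Michaelis-Menten rate laws; LSODA
    time-course simulation with trajectory summaries (endpoint, plateau
    detection, area under the curve); programmatic construction of
    experimental arms (constitutively active ALK-F1174L, crizotinib and
    gefitinib intervention, combination therapy); local finite-difference
    sensitivity analysis of kinetic parameters; bounded least-squares
    kinetic parameter estimation; SBML import and a native YAML network
    format; microarray-style expression validation (log2 transform,
    quantile normalization, fold change); and a seeded synthetic-data
    generator for cascades, noisy time-course observations and expression
    matrices with planted effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    limma,
    xml2,
    yaml,
    jsonlite,
    tools,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
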