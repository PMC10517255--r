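Package: uoxkit
Title: Orthologous Composition Divergence, Ancestral Cysteine Gain/Loss, and Uricase Kinetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolutionary repurposing of vertebrate urate
    oxidase (uricase). Three pipelines are provided: a differential amino-acid
    composition scan across vertebrate orthogroups with volcano-style
    classification; ancestral reconstruction of cysteine presence/absence on a
    phylogeny with per-branch gain/loss counting (Fitch parsimony, ACCTRAN, and
    two-state likelihood models); and kinetic modelling of the uricase reaction
    chain (urate to 5-hydroxyisourate via the urate dianion and
    5-peroxyisourate), including SVD analysis of time-resolved spectra,
    progress-curve fitting, Michaelis-Menten estimation and FOX-assay hydrogen
    peroxide quantification. Synthetic-data generators with recorded ground
    truth support parameter-recovery testing of every pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    ape,
    minpack.lm,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
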