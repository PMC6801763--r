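Package: cspfit
Title: Chemical Shift Perturbation Titration Analysis and Dissociation
    Constant Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of protein-ligand NMR titrations followed by 1H-15N
    HSQC. Computes gyromagnetic-ratio-weighted chemical shift perturbations
    from assigned peak lists, classifies per-residue exchange regimes,
    selects binding-site hotspot residues by the mean plus one standard
    deviation rule, and estimates dissociation constants under a
    ligand-depletion single-site fast-exchange model and a two-site
    (tandem-domain) equilibrium model solved through the cubic free-ligand
    mass balance. Includes a seeded synthetic titration generator for
    end-to-end validation of the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
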