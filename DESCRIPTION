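Package: aqpstruct
Title: Structural Defect Assessment of Aquaporin Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline to assess the structural consequences of
    disease-associated point mutations in human aquaporin water channels.
    Provides PDB structure handling with van der Waals radii and membrane
    topology annotation, template-based side-chain mutagenesis with rotamer
    search, maximal-sphere pore-radius profiling along the channel axis,
    pore-lining residue identification and pore-logo frequency matrices,
    residue contact-map, steric-clash and salt-bridge analysis, a
    finite-difference linearized Poisson-Boltzmann solver for surface
    electrostatics, and a rule-based classifier that assigns each variant to
    one of four structural-defect categories (pore features, tetramer
    assembly, monomer folding, phosphorylation-signal loss). Synthetic
    channel, alignment and variant generators with known ground truth allow
    every stage to be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
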