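Package: epimapr
Title: Structure-Based Epitope Mapping and Antibody-Receptor Interface Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for interpreting antibody-antigen crystal structures of the
    myasthenia gravis type: interfacial contact mapping under a distance rule,
    chemical classification of interface interactions (hydrogen bonds, salt
    bridges, cation-pi, pi-stacking, water-mediated bridges), Shrake-Rupley
    solvent-accessible surface area and buried-surface quantification, hotspot
    calling from per-residue contact profiles, projection of contact profiles
    onto multiple sequence alignments for cross-reactivity prediction, and
    rigid-body modeling of divalent antibody binding to pentameric receptors
    with steric-clash and hinge-geometry feasibility analysis. Includes a
    synthetic-structure generator that builds designed interfaces, analytic
    surface-area bodies, toy pentamers and two-arm antibody dumbbells for
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
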