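Package: mucintools
Title: Mucin-Domain Glycoproteomics, Polymer Dynamics and Dissociation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mucin-domain glycoprotein analysis: glycan composition
    algebra and residual-mass enumeration, theoretical glycopeptide
    fragmentation with oxonium-fingerprint ETD triggering, a deterministic
    manual-validation rulebook (naked-peptide, backbone-coverage and c/z
    site-localization checks), extracted-ion-chromatogram label-free
    quantitation with mass-dependent isotope rules, O-glycoprotease cleavage
    landscape and motif analysis, polymer metrics (persistence length,
    bending angle, height per glycan) on coordinate trajectories, one-phase
    exponential dissociation fits for SPR sensorgrams, and seeded synthetic
    generators for every input with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
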