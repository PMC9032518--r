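Package: atrophysim
Title: Coupled Biomarker Spreading and Morphoelastic Atrophy Simulation of the Aging Brain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.com>
Description: Finite-element simulation of cerebral atrophy in healthy aging and
    Alzheimer's disease. A misfolded-protein biomarker spreads by a
    Fisher-Kolmogorov reaction-diffusion equation over a labeled brain mesh and
    drives region-specific volumetric shrinking through a morphoelastic
    multiplicative split of the deformation gradient with an atrophy-weighted
    compressible neo-Hookean energy. Includes a parametric synthetic brain
    phantom generator (folded cortical ribbon, white-matter core, ventricles,
    hippocampus, cerebrospinal-fluid layer), a quasistatic nonlinear
    equilibrium solver with a staggered coupling driver, and a morphometry
    suite computing region volume fractions, gyrification index, two-way
    nearest-node cortical thickness, and sulcal widening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    grDevices,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
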