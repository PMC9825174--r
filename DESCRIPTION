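Package: smtrack
Title: Single-Molecule Tracking and Kinetics on DNA Tightropes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for single-molecule imaging of DNA-repair
    proteins on stretched DNA: simulation of trajectories, kymographs, dwell
    tables and binding isotherms with known ground truth; kymograph line
    tracking by per-frame Gaussian fitting with blink-gap merging;
    mean-squared-displacement analysis and anomalous-diffusion fitting with
    goodness-of-fit filters; binding-lifetime estimation by survival decay and
    cumulative residence time distributions with photobleaching correction;
    dual-color colocalization and on-target classification against damage-site
    fiducial maps; and equilibrium quantification with the quadratic
    (ligand-depletion) binding isotherm, excision fractions and fold
    stimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    survival,
    tiff
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'colocalization.R'
    'equilibria.R'
    'fgn.R'
    'io.R'
    'kinetics.R'
    'motion.R'
    'pipeline.R'
    'simkit.R'
    'smtrack-package.R'
    'tracking.R'
    'utils-fit.R'
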