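Package: hydroshell
Title: Hydration-Shell Analysis from HDO Difference Spectra and Molecular
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying solute-affected water in aqueous solutions
    of peptides and osmolytes. Extracts the solute-affected HDO spectrum and
    the affected-water number N from FTIR concentration series by
    extrapolation to infinite dilution under a two-state (bulk/affected)
    mixture model; builds theoretical non-interacting affected spectra for
    two-solute mixtures and decomposes the experimental affected water into
    pure-solute and shared/excess contributions under non-negativity
    constraints; computes band-shape parameters and transforms OD-stretch
    bands into oxygen-oxygen distance distributions through an empirical
    frequency-distance correlation; and provides solvation-shell statistics
    (fragment-centred radial distribution functions, distance-binned
    orientation angles, geometric hydrogen-bond counts) from orthorhombic-box
    trajectories. Ground-truthed synthetic generators for both spectra series
    and toy trajectories support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    pracma,
    signal
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'spectrum-methods.R'
    'spectrum-io.R'
    'manifest.R'
    'affected.R'
    'ternary.R'
    'bands.R'
    'synthetic-spectra.R'
    'trajectory-io.R'
    'traj-analysis.R'
    'synthetic-trajectory.R'
    'pipeline.R'
    'hydroshell-package.R'
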