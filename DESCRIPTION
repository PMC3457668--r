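Package: lagrmsd
Title: Lagged RMSD Analysis for Molecular Dynamics Convergence Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects when a molecular dynamics trajectory has not yet
    converged using lagged RMSD analysis. Mean RMSD between configuration
    pairs separated by fixed time lags is fitted with a Hill saturation
    model; the fit is repeated over increasing start offsets and the
    fitted plateau is extrapolated with a monoexponential decay to the
    limiting distance between unrelated configurations. Includes pairwise
    RMSD with optional Kabsch superposition, multi-model PDB and XYZ
    trajectory readers, Ornstein-Uhlenbeck synthetic trajectories with
    closed-form lagged RMSD oracles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
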