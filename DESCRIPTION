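Package: ensdyn
Title: Structural Ensemble Comparison and Solution Dynamics of a Dimeric Ribonuclease Toxin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing X-ray and NMR structural ensembles of small
    dimeric proteins and for analysing the accompanying solution biophysics.
    Includes per-residue pairwise RMSD profiling after Kabsch superposition,
    crystal-lattice contact detection with per-residue buried surface area
    (Shrake-Rupley SASA over symmetry mates), 15N relaxation fitting with
    rotational correlation time estimation, chemical shift perturbation
    mapping, DLS correlogram fitting via the Siegert relation, CD unit
    conversion, electrospray charge-ladder deconvolution, and SAXS Guinier,
    Debye and minimal ensemble search analysis. A seeded synthetic-data
    module generates every input the pipeline consumes so all stages are
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
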