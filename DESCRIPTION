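Package: pnadyn
Title: Torsion Parameterization and Duplex Dynamics Analysis for
    Gamma-Modified Peptide Nucleic Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits CHARMM-style periodic torsion terms (force constant,
    multiplicity, phase) and applies deterministic partial-charge edits for
    substituent linkages on the gamma-PNA backbone, against a target
    torsional energy profile using an offset-invariant pairwise error.
    Also provides the trajectory analysis suite used to characterize
    gamma-PNA duplex destabilization: Kabsch-superposed RMSD and RMSF,
    hydrogen-bond occupancy, backbone torsion distributions, Cartesian
    covariance PCA with k-means conformational substates and centroid
    representative frames, and a base-pair-plane helical-bend metric.
    Includes synthetic generators for scan profiles and idealized duplex
    ensembles with known ground truth, plus readers and writers for
    multi-model PDB, delimited scan and charge tables, and CHARMM
    parameter-stream dihedral stanzas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
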