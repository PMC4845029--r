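Package: SiteAffinity
Title: Structure, Energetics and Gating Kinetics of Nicotinic Receptor
    Agonist Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis toolkit for fetal-versus-adult nicotinic acetylcholine
    receptor agonist sites. Reads multi-model coordinate ensembles and computes
    binding-pocket geometry (aromatic-ring centroids, two-tetrahedron pocket
    volume, beta-hairpin strand axes and twist, torsions, hydrogen-bond
    occupancy), trajectory stability and flexibility metrics (RMSD with region
    exclusion, rolling-drift slopes, per-residue RMSF), an empirically
    calibrated ensemble binding-energy score with exhaustive grid calibration
    of its van der Waals and electrostatic weights, and single-channel gating
    kinetics under the A+C<->AC<->AO scheme (exact dwell-time simulation,
    aggregated-Markov maximum-likelihood rate estimation, Kd and binding-energy
    derivations, background correction, phi-value regression and modal-gating
    analysis). Seeded synthetic generators emulate molecular-dynamics ensembles
    and patch-clamp dwell records so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), methods
Imports:
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
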