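Package: glycanshield
Title: Quantifying N-Glycan Shielding of Ligand Binding Sites from
    Molecular Dynamics Trajectories and NMR Titrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of how N-glycans occlude distinct ligand binding
    modes on a glycoprotein receptor, developed around the CD44
    hyaluronan-binding domain. Computes per-residue minimum-distance
    series and contact fractions from molecular dynamics trajectories,
    the footprint-weighted per-binding-mode glycan coverage statistic
    with replica means and standard errors, inter-glycan contact
    matrices, surface distance maps, ligand association/dissociation
    event detection with hysteresis, Shrake-Rupley solvent-accessible
    surface areas and buried interface areas, and minimal chemical
    shift perturbation profiles with titration-response classification
    for HSQC peak lists. Includes synthetic trajectory and peak-list
    generators with exact planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    bio3d,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
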