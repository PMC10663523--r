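Package: memstates
Title: Orientational States of Membrane-Anchored GTPase Domains from NMR Observables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to analyse how the folded domain of a lipid-anchored GTPase
    distributes over membrane-proximal orientational states. Back-calculates
    paramagnetic relaxation enhancement (PRE) profiles for conformers held
    above a planar bilayer carrying a layer of nitroxide spin labels, selects
    fixed-size conformer ensembles against measured methyl PRE profiles with
    noise-perturbed repeats and population statistics, clusters orientations
    into states and builds potentials of mean force over tilt/spin angles,
    converts deuterium quadrupolar splittings into acyl-chain order parameter
    and mean-torque chain-extension profiles, fits inversion-recovery and
    TRACT relaxation decays, and rescales rotational correlation times across
    temperature and solvent viscosity. A synthetic-data module generates every
    input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
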