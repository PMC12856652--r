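Package: spinmfe
Title: Magnetic Field Effects on Radical-Pair Recombination with Spin Relaxation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spin-dynamics toolkit for magnetic field effects (MFEs) on the
    recombination of radical pairs, motivated by lipid peroxyl radicals in
    membranes. Builds two-radical spin systems with arbitrary nuclear spins,
    assembles stochastic Liouville equations with Haberkorn reaction kinetics,
    and computes singlet/triplet reaction yields by exact Liouville-space
    linear solves. Spin relaxation is treated with Bloch-Redfield-Wangsness
    (BRW) theory: auto-/cross-covariance functions of fluctuating hyperfine
    and g-tensor components are estimated by FFT, fitted with 50 exponential
    decays on a fixed logarithmic lag grid, and converted to spectral
    densities driving hyperfine, g-anisotropy and spin-rotational relaxation
    superoperators. A synthetic-dynamics module generates surrogate dihedral
    and orientation trajectories with controlled correlation times so the
    full pipeline (tensor mapping, covariance fitting, field scans) runs and
    is testable without external molecular-dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
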