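Package: thzwater
Title: Terahertz Absorption Spectra of Water Models from Collective Dipole Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes far-infrared/terahertz absorption coefficients
    alpha(omega)*n'(omega) of liquid water from molecular-dynamics
    trajectories via the collective rotational dipole moment and its
    time derivative, the rotational current.  Supports fixed-charge,
    Drude-polarizable and distributed-multipole (AMOEBA-style)
    electrostatic parameterizations, post-trajectory self-consistent
    induced-dipole polarization, self/cross and permanent/induced
    decompositions of the dielectric response, Savitzky-Golay spectral
    conventions, and a synthetic rigid-water librator generator with
    analytically known correlation functions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
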