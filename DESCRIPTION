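Package: polariqct
Title: Quasi-Classical Trajectories and Anharmonic Spectra of Vibrational
    Polaritons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation toolkit for vibrational strong coupling between a
    hydrogen-bonded molecular dimer and an optical cavity mode. Implements
    the Pauli-Fierz light-matter Hamiltonian in its completed-square form
    over pluggable potential-energy and dipole-moment surfaces, ships an
    analytic permutationally invariant model water-dimer surface, and
    combines a quasi-classical trajectory engine (normal-mode sampling,
    velocity-Verlet propagation, dissociation statistics) with product-state
    analysis by Gaussian binning and a reduced-dimensional cavity VSCF/VCI
    solver for polaritonic infrared spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
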