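Package: etsnocv
Title: Extended-Transition-State Energy Decomposition with Natural Orbitals
    for Chemical Valence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decomposes the interaction energy between two molecular
    fragments into preparation, electrostatic, Pauli-repulsion, orbital,
    dispersion and MP2-correlation contributions (the Ziegler-Rauk extended
    transition-state scheme), and resolves the orbital term into paired
    natural-orbitals-for-chemical-valence charge-flow channels with
    exportable deformation-density cube files. Includes a self-contained
    Hartree-Fock / MP2 backend with analytic Gaussian integrals over a
    built-in minimal basis, fragment/promolecule construction via Schmidt
    orthogonalization, spin-resolved open-shell analysis, and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
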