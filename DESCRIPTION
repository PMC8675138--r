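Package: mlscf
Title: Multilevel Hartree-Fock with Screened Fock Matrix Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multilevel Hartree-Fock (MLHF) for closed-shell molecules: the
    total density is split into an active density, optimized by a reduced-space
    self-consistent field, and a frozen environment density. The two-electron
    Fock contributions are built directly from shell-quartet electron-repulsion
    integrals with Cauchy-Schwarz screening augmented by per-shell maxima of
    the active molecular-orbital coefficients, so that the environment
    contribution is built once at linear-scaling cost and the active
    contribution at system-size-independent cost. Includes a Gaussian integral
    engine (s and p shells; STO-3G and 6-31G), SAD and SMD starting guesses
    with McWeeny purification, restricted partial Cholesky localization of the
    occupied space, projected atomic orbitals for the active virtual space,
    DIIS-accelerated Roothaan-Hall iterations, and a conventional restricted
    Hartree-Fock reference mode.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
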