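Package: plafep
Title: Coarse-Grained Alchemical Free-Energy Scans for Phospholipid
    Prodrug Linker Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks phospholipid-drug (PL-prodrug) conjugates by their
    phospholipase A2 transition-state binding free energy as a function of
    the CH2 linker length separating the sn-2 ester from the drug moiety.
    Implements the two-step alchemical protocol on coarse-grained surrogate
    systems: thermodynamic integration over a polynomial mixing Hamiltonian
    (Gauss-Legendre quadrature) for removal of terminal linker units, then
    umbrella sampling with weighted-histogram (WHAM) unbiasing for
    re-attachment of the drug moiety, assembled into thermodynamic cycles
    that yield relative transition-state binding free energies and relative
    hydrolysis rates across linker lengths in water and lipid reference
    phases. Includes a BAOAB Langevin dynamics engine with holonomic
    distance constraints, block-averaged error estimation, forward/backward
    hysteresis errors, synthetic pocket fixtures, and tidy result objects
    with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    pracma,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
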