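Package: excitonsim
Title: Quantum and Classical Exciton Transport in B850 Pigment Nanoarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates excitation energy transfer in mesoscale arrays of B850
    bacteriochlorophyll rings from the light-harvesting 2 complex of purple
    bacteria. A fully quantum route propagates the Davydov D1 trial state for
    the Holstein exciton-phonon Hamiltonian under the Dirac-Frenkel
    time-dependent variational principle and extracts reduced density
    matrices, ring populations, mean-square displacements, anomalous
    diffusion exponents, coherence sizes, superradiance enhancement factors
    and absorption spectra. A classical route solves nearest-neighbour
    incoherent hopping master equations on 1D chains and 2D hexagonal
    lattices, with closed-form stationary and Bessel-function time-dependent
    solutions and exciton diffusion lengths. Adaptive fractal analysis of
    population time series yields Hurst exponents, with a fractional
    Brownian motion generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Matrix,
    deSolve,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
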