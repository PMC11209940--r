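Package: afmatch
Title: Adaptive Force Matching for Alkane Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parameterizes molecular-mechanics force fields for linear and
    cyclic alkanes by adaptive force matching (AFM): a harmonic
    bonded / exponential-repulsion / damped C6+C8 dispersion energy
    expression is fitted to reference atomic forces by linear least squares
    (singular value decomposition), partial charges are extracted from
    fitted charge products by charge matrix decomposition (CMD, the scaled
    dominant eigenvector of the charge-product matrix), and dispersion
    coefficients are fitted separately to dimer dispersion energies.
    Includes a Langevin (BAOAB) conformational sampler, radial distribution
    function convergence diagnostics for the iterative AFM loop, analytic
    1/r^6 and 1/r^8 long-range tail corrections to energy and pressure with
    barostat set-point logic, and a synthetic reference generator that
    emulates quantum-chemistry cluster forces and dimer dispersion energies
    from a known ground-truth parameter set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
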