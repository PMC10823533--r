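Package: hoprates
Title: Nonadiabatic Electron-Transfer Rates by Surface Hopping (MASH and FSSH)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory surface-hopping simulations of electron transfer in the
    two-state Brownian-oscillator spin-boson model, with both the mapping
    approach to surface hopping (MASH, deterministic hops driven by the sign of
    the Bloch-vector z component) and Tully's fewest-switches surface hopping
    (FSSH, stochastic hops).  Nuclear motion is integrated with a BAOAB
    Langevin scheme on the active adiabatic surface; the electronic two-level
    system is propagated with the exact piecewise-constant-field propagator.
    Includes classical Boltzmann initial-condition sampling restricted to the
    reactant region, hemisphere (|Sz|-weighted) electronic sampling for MASH,
    energy-gap-triggered decoherence corrections, product-population curves
    with hop-count decompositions, plateau-slope and full-decay rate
    estimators, and the closed-form Marcus-theory benchmark rate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
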