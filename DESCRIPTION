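Package: splitgas
Title: Stochastic SplitGAS: Effective-Hamiltonian Multireference CI by Walker Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Uncontracted multireference perturbation theory over generalized
    active spaces (GAS). A GAS partition splits the configuration space into a
    principal (P) and a perturber (Q) block of supergroups; Loewdin downfolding
    truncated at second order yields an effective Hamiltonian whose QQ block is
    diagonal. The package solves that Hamiltonian both deterministically (exact
    diagonalization and self-consistent downfolding) and stochastically, by full
    configuration interaction quantum Monte Carlo (FCIQMC) imaginary-time walker
    dynamics with supergroup-constrained precomputed heat-bath (PCHB) excitation
    generation via alias tables. Includes FCIDUMP integral input/output, synthetic
    integral generators (Hubbard chains, random two-electron tensors), Slater-Condon
    matrix elements over bit-encoded determinants, spin-adapted (S^2-projected)
    bases, blocking-analysis error bars, and wavefunction-deviation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
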