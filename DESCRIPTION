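Package: drudeqmc
Title: Quantum Monte Carlo for Electrons Embedded in Quantum Drude Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variational and diffusion Monte Carlo for a joint Hamiltonian
    coupling an explicit electronic subsystem (nuclei, electrons with a
    Slater-Jastrow ansatz) to a polarizable environment of charged quantum
    harmonic oscillators (quantum Drude oscillators) plus fixed point
    charges. Short-range damping of the Coulomb coupling (erf, Gaussian,
    fourth-power exponential and s-wave kernels) cures overpolarization of
    the electrons onto environment charges. Includes stochastic
    reconfiguration optimization of the ansatz, closed-form coupled-dipole
    and grid-diagonalization reference oracles, TIP4P-style water
    construction, cage-deformation machinery, and potential-energy-surface,
    solvation-energy and binding-energy-change analysis with uncertainty
    propagation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
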