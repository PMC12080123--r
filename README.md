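# drudeqmc

Variational and diffusion Monte Carlo for an explicit electronic
subsystem embedded in a polarizable environment of **quantum Drude
oscillators** (QDOs) and fixed point charges.

A QDO is a coarse-grained atom or molecule: a fixed center of charge
$+q$ plus a distinguishable quantum particle (*drudon*) of charge $-q$
and mass $\mu$ in a harmonic well of frequency $\omega$, parametrized so
the oscillator reproduces the species' dipole polarizability
$\alpha = q^2/(\mu\omega^2)$ and leading dispersion coefficients. Coupling
a bath of such oscillators (plus TIP4P-style point charges for molecular
electrostatics) to an explicit electron/nucleus subsystem gives a joint
Hamiltonian

$$\hat H \;=\; \hat H^{e}\;+\;\hat H^{Q}\;+\;\hat V^{e\text{-}Q},$$

whose cross coupling $\hat V^{e\text{-}Q}$ carries electrostatics,
polarization and dispersion between subsystem and environment — but also
an *overpolarization* catastrophe at short range, where electrons drift
onto the positive environment charges. The package regularizes every
electron–environment and intra-environment Coulomb pair with a
short-range damping kernel $m(r)/r$ (erf, Gaussian, fourth-power
exponential, or s-wave form; pair length
$\sigma_{ij}=\sqrt{\sigma_i\sigma_j}$) and integrates the joint system by:

* **VMC** over a three-factor ansatz — electronic Slater–Jastrow ×
  drudonic Gaussian $\exp(-\tfrac12 \bar d^\top A \bar d)$ × positive
  dipolar coupling $\exp(\boldsymbol\mu_e^\top B\,\bar d)$ — with
  automatic 50%-acceptance step tuning and blocked error bars;
* **stochastic reconfiguration** optimization of the ansatz parameters
  with correlated-sampling reuse of the walker sample;
* **fixed-node DMC** with Umrigar-rescaled drift, mass-scaled
  per-particle time steps, capped local energies and a
  weight-conserving population comb (drudons are nodeless, so DMC is
  exact for pure-QDO systems regardless of the ansatz);
* closed-form **reference oracles** (isolated-QDO energies,
  coupled-dipole normal modes with the $-C_6/R^6$ asymptote, grid
  diagonalization) that anchor every stochastic result;
* **analysis** tools: PES scans with an overpolarization variance flag,
  solvation energies, environment-induced binding-energy changes, cage
  deformation and synthetic water-cage fixtures.

See the methods vignette (`vignettes/methods.Rmd`) for the model,
ansatz, algorithms and design choices in full.

## Worked example

A single argon-parameter QDO. With the exact Gaussian ansatz
($A=\mu\omega I$) VMC is zero-variance exact; with a deliberately wrong
ansatz VMC is variationally above the true energy, and nodeless DMC
projects back to it:

```r
library(drudeqmc)

p <- qdo_params("Ar")                      # q = 1.3314, w = 0.7272, mu = 0.3020
sys <- el_qdo_system(qdos = list(qdo_spec(c(0, 0, 0), p$q, p$mu, p$omega)))

run_vmc(ansatz_parameters(sys), sys,
        vmc_settings(n_steps = 200, n_walkers = 100, seed = 1))
#> E = 1.090800 +/- 0.000000 hartree  (var 1.852e-32, n_eff 20000)

wrong <- ansatz_parameters(sys, A = 1.3 * p$mu * p$omega * diag(3))
run_vmc(wrong, sys, vmc_settings(n_steps = 300, n_walkers = 150, seed = 1))
#> E = 1.135780 +/- 0.002050 hartree  (var 5.132e-02, n_eff 10423)

run_dmc(wrong, sys, dmc_settings(target_population = 200, n_blocks = 25,
                                 steps_per_block = 80, seed = 1))
#> E = 1.099751 +/- 0.007336 hartree  (var 6.472e-02, n_eff 14)

isolated_qdo_energy(sys$qdos[[1]])
#> [1] 1.0908
```

The exact ground state is $\tfrac32\omega = 1.0908$ hartree: the exact
ansatz reproduces it with variance at machine precision, the wrong
ansatz sits ~0.045 Ha above it at VMC level, and DMC recovers it within
its error bar.

A YAML-driven run (see `?load_run_config` for the schema) and a thin
command-line front end are also available:

```sh
Rscript inst/scripts/qmc_cli.R run config.yml --out result.json
Rscript inst/scripts/qmc_cli.R fixtures 8 6.0 1 cage.xyz
```

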