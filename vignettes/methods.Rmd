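---
title: "Quantum Monte Carlo for electrons in a Drude-oscillator environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum Monte Carlo for electrons in a Drude-oscillator environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drudeqmc)
```

## The model

A quantum Drude oscillator (QDO) is a coarse-grained model of an atom or
molecule: a fixed center of charge $+q$ and a distinguishable, spinless
quantum particle (the *drudon*) of charge $-q$ and mass $\mu$, bound to the
center by a harmonic well of frequency $\omega$. The three parameters are
fitted so the oscillator reproduces the species' leading-order response:
its dipole polarizability $\alpha = q^2/(\mu\omega^2)$ and, through the
quantum fluctuations of the bound charge, its leading dispersion
coefficients. Built-in parameter sets (atomic units) are provided for
argon ($q = 1.3314$, $\omega = 0.7272$, $\mu = 0.3020$) and water
($q = 1.1973$, $\omega = 0.6287$, $\mu = 0.3656$). Molecular
electrostatics enter through fixed point charges attached to a parental
QDO; for water these are the four-site TIP4P charges ($+0.605$ on each
hydrogen, $-1.21$ on the M site placed on the HOH bisector 0.2667 Å from
the oxygen), with the oxygen itself carrying no charge.

`drudeqmc` couples such an environment to an explicit electronic
subsystem (nuclei plus electrons). The total Hamiltonian is the standard
Born–Oppenheimer electronic Hamiltonian (bare Coulomb), plus the internal
QDO/point-charge Hamiltonian, plus the Coulomb coupling between the two
subsystems. Interaction bookkeeping: a drudon interacts with everything
except its own center (where the harmonic well replaces Coulomb) and its
parental point charges; by default a center also skips its own (rigid,
constant) point charges, a flag the user can change. All other fixed-fixed
pair energies are constants that are included, because they matter for
solvation-energy differences.

### Damped Coulomb coupling

With bare Coulomb coupling, electrons can drift onto the positive
environment charges (the center $+q$ or positive point charges): the
*overpolarization* or charge-spilling catastrophe familiar from QM/MM.
Every pair involving at least one environment member is therefore screened
by a multiplicative kernel $m(r) \in [0,1]$, finite at contact and
approaching 1 at long range, so the pair energy is $q_i q_j\, m(r)/r$.
The purely electronic terms (electron–electron, electron–nucleus,
nucleus–nucleus) are never damped. Four kernels from the QM/MM and Drude
literature are implemented:

* `erf`: $m(r) = \mathrm{erf}(r/\sigma)$,
* `exp2`: $m(r) = 1 - e^{-(r/\sigma)^2}$,
* `exp4`: $m(r) = 1 - e^{-(r/\sigma)^4}$,
* `swave`: $m(r) = 1 - (1 + r/\sigma)\,e^{-2r/\sigma}$ (the potential of
  a 1s charge cloud).

The pair damping length is the geometric mean
$\sigma_{ij} = \sqrt{\sigma_i \sigma_j}$ of the two particles' lengths;
$\sigma = 0$ on either side propagates bare Coulomb, which makes turning
damping off exact rather than approximate. A single global
$\sigma = 0.5$ bohr is the default; species can override it.

Where the water QDO sits is a modelling choice this package makes
explicit: by default the oscillator is attached at the M site (the
center of charge of the four-site model), with `center_site = "O"`
available.

## The trial wave function

The ansatz is a product of three factors.

1. **Electronic Slater–Jastrow.** Spin-up and spin-down Slater
   determinants over fixed molecular orbitals (contracted Cartesian
   Gaussians read from a JSON file, or the built-in hydrogenic `sto`
   orbitals for the all-electron test atoms). The Jastrow has a
   homogeneous two-body term
   $u(r) = c\,r/(1 + b r) + \sum_n g_n e^{-\zeta_n r^2}$ with the Kato
   cusp coefficients $c = 1/4$ (parallel spins) and $c = 1/2$
   (antiparallel), plus an inhomogeneous three/four-body term
   $\sum_{i<j} \chi(\mathbf r_i)^\top \Gamma\, \chi(\mathbf r_j)$ over an
   atomic-orbital basis (3s2p1d-style shells on heavy atoms, 2s1p on
   hydrogen), with $\Gamma$ symmetric so the factor is exchange-symmetric.
   The pair sum is accumulated from precomputed per-electron basis
   projections, so one evaluation costs $O(N_e^2)$ vector products (the
   test suite regression-fits this cost exponent).
2. **Drudonic Gaussian.** $\exp(-\tfrac12 \bar d^\top A \bar d)$ over the
   stacked displacements of all drudons from their centers, $A$ symmetric
   positive definite with $3N_Q(3N_Q+1)/2$ free parameters; for
   noninteracting QDOs the exact ground state is $A = \mu\omega I$. The
   factor has no nodes, which is why diffusion Monte Carlo is exact for
   pure-drudon systems regardless of $A$.
3. **Electron–drudon coupling.** $\exp(\boldsymbol\mu_e^\top B \bar d)$,
   where $\boldsymbol\mu_e = \sum_i Z_i \mathbf R_i - \sum_j \mathbf r_j$
   is the electronic dipole moment and $B$ holds $3\times 3N_Q$ free
   parameters. The dipole origin convention (nuclear-charge weighted) is
   fixed for reproducibility; any constant shift is absorbed into the
   optimum of $B$. The factor is strictly positive, so it deforms but
   never creates nodes.

Local energies are assembled per particle from log-derivatives,
$\nabla^2\Psi/\Psi = \nabla^2\log\Psi + |\nabla\log\Psi|^2$, with
analytic gradients and Laplacians for every factor (each is checked
against central finite differences in the test suite). A determinant with
magnitude below $10^{-300}$ is treated as a node.

## Sampling and optimization

**VMC.** Walkers are updated particle by particle (electrons first, then
drudons, each block in random order) with Gaussian proposals of amplitude
$\delta/\sqrt{m}$ per species, accepted with probability
$\min(1, |\Psi'/\Psi|^2)$. The two amplitudes are tuned before production
by multiplicative feedback $\delta \leftarrow \delta\,\mathrm{clip}(a/0.5,
0.5, 2)$ until the measured acceptance of each species is within
$50\% \pm 2\%$, the standard compromise between step size and
autocorrelation. Error bars come from a blocking analysis (block-size
doubling until the estimate plateaus); the error-bar calibration is
itself tested against the spread of independent seeds. The engine
evaluates the whole walker population as a batch for each single-particle
move — in R, vectorizing across walkers is the efficient axis, and it
leaves the algorithm unchanged.

**Stochastic reconfiguration.** Parameters (Jastrow, $\Gamma$, $A$, $B$;
orbital coefficients stay fixed) are optimized with
$\Delta p = -\delta t\,(S + \varepsilon I)^{-1} g$, where $S$ is the
covariance of the log-derivatives $O_k = \partial_k \log|\Psi|$ and
$g_k = 2\,\mathrm{cov}(E_L, O_k)$, with $\varepsilon = 10^{-3}$ doubled
whenever the solve fails. Between updates the current sample is reused
with correlated-sampling weights $w = |\Psi_{\text{new}}/
\Psi_{\text{old}}|^2$; when the normalized overlap proxy
$\langle w\rangle^2/\langle w^2\rangle$ drops below 0.95 (a value the
source literature leaves open; it is configurable) the sample is redrawn.
A raw update that breaks the constraints is repaired: $A$ is projected
back to positive definite through an eigenvalue floor, Jastrow exponents
are floored at small positive values.

**DMC.** Fixed-node diffusion Monte Carlo with importance sampling:
particle-by-particle drift–diffusion with per-particle time steps
$\tau_i = \delta\tau/m_i$ (mirroring the VMC mass scaling), the
Umrigar-rescaled drift $\bar v = v\,(-1 + \sqrt{1 + 2|v|^2\tau})/(|v|^2
\tau)$, and an accept/reject step against the importance-sampled Green's
function with the effective time step rescaled by the accepted/proposed
squared displacement ratio. Electron moves that flip the determinant sign
are rejected (fixed node); drudon moves are never node-checked. Weights
multiply by $\exp(-\tau_{\text{eff}}(\bar E_L - E_{\text{ref}}))$ with
local energies capped at $E_{\text{est}} \pm \alpha\sqrt{N/\tau}$
($\alpha = 0.2$; the hard clip at this scale is used since the source
only cites the scheme). Population control uses a total-weight-preserving
systematic comb every step, with the reference energy updated per step as
$E_{\text{ref}} = E_{\text{est}} - \ln(W/W_{\text{target}})/\delta\tau$;
a per-block update at this gain is unstable, and the per-step form was
verified unbiased against an independent plain-Langevin reference
implementation. The reported energy is the weighted mixed estimator with
blocked error bars; `run_dmc_tau_series()` drives time-step
extrapolations. Default $\delta\tau = 0.005$ a.u.

### A measured limitation of the hard local-energy cap

The cap bound $\alpha\sqrt{N/\tau}$ is calibrated for production-scale
particle numbers. On a *one-particle* toy with a grossly wrong drudon
Gaussian ($A = 2\mu\omega I$), the bound (≈4 Ha at $\tau = 0.005$)
overlaps the physical left tail of the local-energy distribution, the cap
fires on ~1% of samples, and the projected energy acquires a measurable
bias (≈ +0.05 Ha) that disappears when the cap is released. The
DMC-exactness checks therefore use a deliberately wrong but sane ansatz
($A = 1.3\mu\omega I$, whose VMC energy is distinguishable from the exact
$\tfrac32\omega$ at many standard errors while the cap stays inactive),
and the overpolarization scan below widens the cap to the
production-scale bound. Both choices are about keeping a
small-$N$ regularizer from masking the physics being tested.

## Reference oracles

Stochastic results are anchored to deterministic references that share no
code with the QMC paths beyond the damping kernels:

* isolated-QDO energy $\tfrac32\omega$ and polarizability
  $q^2/(\mu\omega^2)$;
* the exact normal-mode ground state of dipole-coupled oscillators
  ($E_0 = \tfrac12\sum_k \sqrt{\lambda_k}$ of the mass-weighted
  force-constant matrix), with the $-C_6/R^6$ asymptote,
  $C_6 = \tfrac34\alpha^2\omega$ for identical QDOs, reproduced to 1% at
  $R = 40$ bohr — the package's `qdo_coupling = "dipole"` mode builds the
  matching Hamiltonian so DMC can be compared to the closed form;
* a dense finite-difference grid eigensolver (3-point or 5-point
  Laplacian) for 1D and radial s-wave toy problems, e.g. the hydrogen
  atom and bound states of the damped-Coulomb well.

## Observables

`interaction_energy()`, `solvation_energy()` and
`binding_energy_change()` implement the supermolecular differences with
quadrature error propagation; runs carrying configuration metadata are
refused if the model settings differ. `pes_scan()` dispatches one run per
grid point (independent seeds per point; correlated-sampling differences
across systems are deliberately out of scope) and marks points whose raw
local-energy variance exceeds 10× the scan median — the operational
overpolarization diagnostic. `deform_cage()` implements the radial cage
deformation: each water's oxygen moves by $dR$ along the unit vector from
the subsystem's nuclear geometric center, hydrogens rigidly translated so
the intramolecular geometry is exactly preserved.
`generate_fixture_cage()` builds synthetic spherical shells of rigid
TIP4P-geometry waters ($r_{\mathrm{OH}} = 0.9572$ Å,
$\angle\mathrm{HOH} = 104.52^\circ$, O–O $> 2.4$ Å, seeded), standing in
for externally produced cage snapshots.

## What the synthetic studies do and do not show

The bundled studies run at desk scale: single oscillators, oscillator
dimers, hydrogen, and an electron+QDO toy, with walker populations of
100–250 and $10^3$–$10^4$ steps (sizes chosen so the whole suite runs in
minutes). They exercise exactness properties (zero variance on exact
eigenstates, nodeless-DMC convergence, coupled-dipole agreement,
parameter recovery) rather than production observables. Passing them
shows the machinery is correct; it does not show that the fixed-orbital
ansatz family is accurate for large molecular systems, where orbital
quality, pseudopotentials (out of scope here) and exchange repulsion
(absent from the model by construction) dominate. The overpolarization
scan is qualitative by design: with a fixed 1s trial orbital the bare
short-range catastrophe appears as a quasi-stationary high-variance
state rather than a literal divergence, and the variance flag is the
contrast that is robust across seeds.

## Numerical choices

* Atomic units internally; geometry files in Å
  (1 Å = 1.8897259886 bohr); results also reported in meV
  (1 Ha = 27211.386245988 meV).
* One base-R RNG stream per run, seeded from the settings; runs are
  bit-reproducible given (seed, n_walkers).
* Blocking stderr uses block-size doubling down to ≥8 blocks and takes
  the plateau (maximum) estimate.
* SR regularization $\varepsilon = 10^{-3}$, doubling on failed solves;
  eigenvalue floor $10^{-6}$ for the $A$ projection.
* Checkpoints and block logs are JSON/JSON-lines; scans export CSV and
  JSON.
* The acceptance-rate measurement, PES scans and the command-line front
  end (`inst/scripts/qmc_cli.R`) are thin layers over the exported
  functions.

## Known limitations

* No pseudopotentials, multideterminant expansions, backflow, orbital
  optimization, periodic boundary conditions, or exchange-repulsion
  terms; environment waters are rigid.
* The hard local-energy cap biases small-particle-number DMC when the
  trial function is grossly wrong (quantified above).
* Slater determinants with more than one electron per spin channel are
  evaluated walker-by-walker (dense `solve`), which is fine for the
  intended test-atom scale but not tuned for large electron counts.
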