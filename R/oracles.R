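#' Closed-form and brute-force reference oracles
#'
#' Deterministic references that anchor the stochastic results: exact
#' isolated-QDO energies and response properties, normal-mode
#' diagonalization of dipole-coupled oscillators, and a finite-difference
#' grid eigensolver for 1D/radial toy problems. These share no evaluation
#' code with the QMC paths beyond the damping kernels.
#'
#' @name reference_oracles
NULL

#' Ground-state energy of an isolated QDO
#'
#' A QDO is a 3D isotropic harmonic oscillator: E_0 = (3/2) omega.
#'
#' @param spec a [qdo_spec()]
#' @return energy, hartree
#' @export
isolated_qdo_energy <- function(spec) {
  1.5 * spec$omega
}

#' Static dipole polarizability of a QDO
#'
#' alpha = q^2 / (mu omega^2), the leading-order response relation used to
#' parametrize QDOs.
#'
#' @param spec a [qdo_spec()]
#' @return polarizability, a.u.
#' @export
qdo_polarizability <- function(spec) {
  spec$q^2 / (spec$mu * spec$omega^2)
}

#' Leading dispersion coefficient of two identical QDOs
#'
#' C6 = (3/4) alpha^2 omega for two identical oscillators; used only as an
#' asymptotic check of the coupled-dipole solution.
#'
#' @param spec a [qdo_spec()]
#' @return C6, a.u.
#' @export
qdo_c6 <- function(spec) {
  0.75 * qdo_polarizability(spec)^2 * spec$omega
}

#' Exact ground-state energy of dipole-coupled QDOs
#'
#' Drude oscillators whose Coulomb coupling is truncated at dipole order
#' form a quadratic Hamiltonian: with the 3x3 dipole tensor
#' T_ij = (I - 3 nhat nhat')/R^3 between centers, the force-constant matrix
#' K has blocks mu_i omega_i^2 I on the diagonal and q_i q_j T_ij off it.
#' The ground state is E_0 = 1/2 sum_k sqrt(lambda_k) over the eigenvalues
#' of the mass-weighted matrix M^{-1/2} K M^{-1/2}.
#'
#' @param specs list of [qdo_spec()]
#' @return list with `energy` (hartree), `frequencies` (normal-mode
#'   omegas), `interaction` (energy minus the isolated sum)
#' @export
coupled_dipole_energy <- function(specs) {
  n <- length(specs)
  stopifnot(n >= 1)
  K <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    blk <- 3 * (i - 1) + 1:3
    K[blk, blk] <- diag(specs[[i]]$mu * specs[[i]]$omega^2, 3)
  }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      Rij <- specs[[j]]$center - specs[[i]]$center
      R <- sqrt(sum(Rij^2))
      if (R < 1e-10) stop("coupled_dipole_energy: coincident centers")
      nh <- Rij / R
      Tij <- (diag(3) - 3 * outer(nh, nh)) / R^3
      cpl <- specs[[i]]$q * specs[[j]]$q * Tij
      bi <- 3 * (i - 1) + 1:3; bj <- 3 * (j - 1) + 1:3
      K[bi, bj] <- cpl
      K[bj, bi] <- t(cpl)
    }
  }
  minv <- rep(1 / sqrt(vapply(specs, `[[`, 0, "mu")), each = 3)
  D <- K * outer(minv, minv)
  lam <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) <= 0) {
    stop("coupled_dipole_energy: imaginary normal mode (separation inside ",
         "the polarization-catastrophe radius)")
  }
  energy <- 0.5 * sum(sqrt(lam))
  isolated <- sum(vapply(specs, isolated_qdo_energy, 0))
  list(energy = energy, frequencies = sqrt(lam),
       interaction = energy - isolated)
}

#' Lowest eigenvalues of a 1D (or radial) Hamiltonian on a grid
#'
#' Dense finite-difference diagonalization of
#' H = -1/(2m) d^2/dx^2 + V(x) with Dirichlet boundaries: the standard
#' brute-force oracle for bound states of damped-Coulomb and harmonic toy
#' problems. For a radial s-wave problem pass the reduced potential V(r)
#' on r > 0 (the solver then acts on u(r) = r R(r)).
#'
#' @param V potential values on the grid (vector)
#' @param x grid points (uniform spacing)
#' @param mass particle mass
#' @param n_eigen number of lowest eigenvalues to return
#' @param order finite-difference order of the Laplacian: 2 (3-point) or 4
#'   (5-point; much more accurate for smooth potentials)
#' @return numeric vector of eigenvalues (hartree), ascending
#' @export
grid_eigensolve <- function(V, x, mass = 1, n_eigen = 1, order = 2) {
  n <- length(x)
  stopifnot(length(V) == n, n >= 10, order %in% c(2, 4))
  h <- diff(x)
  if (max(abs(h - h[1])) > 1e-9 * h[1]) {
    stop("grid_eigensolve: grid must be uniform")
  }
  h <- h[1]
  k <- 1 / (2 * mass * h^2)
  H <- matrix(0, n, n)
  if (order == 2) {
    diag(H) <- 2 * k + V
    H[cbind(1:(n - 1), 2:n)] <- -k
    H[cbind(2:n, 1:(n - 1))] <- -k
  } else {
    diag(H) <- (30 / 12) * k + V
    H[cbind(1:(n - 1), 2:n)] <- -(16 / 12) * k
    H[cbind(2:n, 1:(n - 1))] <- -(16 / 12) * k
    H[cbind(1:(n - 2), 3:n)] <- (1 / 12) * k
    H[cbind(3:n, 1:(n - 2))] <- (1 / 12) * k
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  sort(ev)[seq_len(n_eigen)]
}

#' Ground state of a radial s-wave two-body problem
#'
#' Convenience wrapper around [grid_eigensolve()] for s-wave problems
#' -1/(2m) u'' + V(r) u = E u on (0, r_max] with u(0) = u(r_max) = 0.
#'
#' @param Vfun potential function of r (hartree)
#' @param mass reduced mass
#' @param r_max box radius, bohr
#' @param n grid points
#' @param order finite-difference order (see [grid_eigensolve()])
#' @return ground-state energy, hartree
#' @export
radial_ground_state <- function(Vfun, mass = 1, r_max = 40, n = 2000,
                                order = 2) {
  r <- seq(r_max / n, r_max, length.out = n)
  grid_eigensolve(Vfun(r), r, mass = mass, n_eigen = 1, order = order)
}
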