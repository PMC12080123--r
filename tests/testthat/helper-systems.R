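# Shared fixture builders (all generated in code; atomic units)

ar_qdo_system <- function(center = c(0, 0, 0), ...) {
  p <- qdo_params("Ar")
  el_qdo_system(qdos = list(qdo_spec(center, p$q, p$mu, p$omega)), ...)
}

# exact and deliberately-wrong drudon ansatz for one Ar QDO
ar_exact_params <- function(system) ansatz_parameters(system)
ar_wrong_params <- function(system, factor = 2) {
  p <- qdo_params("Ar")
  ansatz_parameters(system, A = factor * p$mu * p$omega * diag(3))
}

h_atom_system <- function(Rn = c(0, 0, 0)) {
  el_qdo_system(nuclei = list(nucleus(Rn, 1)), n_up = 1)
}

h_atom_params <- function(system, zeta = 1) {
  ansatz_parameters(system, mo = hydrogen_1s(system$nuclei[[1]]$position,
                                             zeta = zeta))
}

# electron + Ar QDO toy used for the overpolarization diagnostics
electron_qdo_toy <- function(R, damping = "erf", sigma = 0.5) {
  p <- qdo_params("Ar")
  el_qdo_system(
    nuclei = list(nucleus(c(0, 0, 0), 1)), n_up = 1,
    qdos = list(qdo_spec(c(0, 0, R), p$q, p$mu, p$omega)),
    damping = damping, sigma = if (damping == "none") 0 else sigma)
}

# a fully-featured small mixed system exercising every wave-function term
rich_test_setup <- function(seed = 42) {
  set.seed(seed)
  nuc <- list(nucleus(c(0, 0, 0), 2), nucleus(c(2, 0, 0), 1))
  pA <- qdo_params("Ar")
  qd <- list(qdo_spec(c(0, 0, 4), pA$q, pA$mu, pA$omega),
             qdo_spec(c(4, 0, 4), 1.0, 0.5, 0.9))
  pcs <- list(point_charge(c(0, 1, 4), 0.3, parent = 1L),
              point_charge(c(4, 1, 4), -0.3, parent = 2L))
  sys <- el_qdo_system(nuclei = nuc, n_up = 2, n_down = 1, qdos = qd,
                       point_charges = pcs, damping = "erf", sigma = 0.5)
  bas <- list(
    basis_function(c(0, 0, 0), exponents = c(1.5, 0.4),
                   coefficients = c(0.7, 0.4)),
    basis_function(c(2, 0, 0), exponents = 0.8),
    basis_function(c(0, 0, 0), l = c(1, 0, 0), exponents = 0.6))
  mo <- mo_set(bas, matrix(c(1, 0.2, 0.1, 0.3, 1, 0.2), 3, 2))
  jb <- default_jastrow_basis(nuc, scale = 0.9)
  qj <- length(jb)
  gam <- matrix(stats::rnorm(qj^2, sd = 0.02), qj, qj)
  gam <- (gam + t(gam)) / 2
  Araw <- matrix(stats::rnorm(36, sd = 0.05), 6, 6)
  A <- crossprod(Araw) + diag(0.3, 6)
  B <- matrix(stats::rnorm(18, sd = 0.03), 3, 6)
  params <- ansatz_parameters(
    sys, mo = mo,
    jastrow_pair = list(b_p = 1.2, b_a = 0.8, g_p = 0.1, zeta_p = 0.5,
                        g_a = -0.05, zeta_a = 0.7),
    jastrow_basis = jb, gamma = gam, A = A, B = B)
  walker <- walker_configuration(
    electrons = matrix(stats::rnorm(9, sd = 1.2), 3, 3),
    drudons = rbind(c(0, 0, 4), c(4, 0, 4)) +
      matrix(stats::rnorm(6, sd = 0.5), 2, 3))
  list(system = sys, params = params, walker = walker)
}

# numeric gradient/Laplacian of log|Psi| for one particle (central FD)
fd_grad_lap <- function(params, system, walker, p, h = 1e-5) {
  ne <- nrow(walker$electrons)
  f <- function(w) log_abs_psi(params, system, w)$log
  shift <- function(w, c3, d) {
    if (p <= ne) w$electrons[p, c3] <- w$electrons[p, c3] + d
    else w$drudons[p - ne, c3] <- w$drudons[p - ne, c3] + d
    w
  }
  f0 <- f(walker)
  g <- numeric(3); lap <- 0
  for (c3 in 1:3) {
    fp <- f(shift(walker, c3, h)); fm <- f(shift(walker, c3, -h))
    g[c3] <- (fp - fm) / (2 * h)
    lap <- lap + (fp + fm - 2 * f0) / h^2
  }
  list(grad = g, lap = lap)
}

# orthogonal-ish dummy orbital set wide enough for n electrons of one spin
dummy_mo <- function(n) {
  bas <- lapply(seq_len(n), function(i) {
    basis_function(c(0.3 * i, 0, 0), exponents = 0.4 + 0.25 * i)
  })
  mo_set(bas, diag(n))
}
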