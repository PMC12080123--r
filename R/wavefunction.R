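#' Trial wave function for the joint electron + QDO system
#'
#' The ansatz is a product of three factors:
#' \enumerate{
#'   \item an electronic Slater-Jastrow part: spin-up and spin-down Slater
#'     determinants over fixed molecular orbitals, a homogeneous two-body
#'     Jastrow (spin-resolved Pade cusp term plus Gaussian remodulation) and
#'     an inhomogeneous three/four-body Jastrow over an atomic-orbital basis;
#'   \item a drudonic Gaussian exp(-1/2 d' A d) over the stacked
#'     displacements d of all drudons from their centers, with A symmetric
#'     positive definite (A = mu*omega*I is the exact isolated-QDO ground
#'     state);
#'   \item a positive electron-drudon coupling exp(mu_e' B d), where mu_e is
#'     the electronic dipole moment sum_i Z_i R_i - sum_j r_j (a dipolar
#'     approximation of the cross correlation).
#' }
#' Pure electronic or pure QDO systems use only the corresponding factor.
#'
#' @param system an [el_qdo_system()]
#' @param mo an [mo_set()]; required when the system has electrons
#' @param jastrow_pair list with cusp parameters `b_p`, `b_a` (> 0) and
#'   Gaussian remodulation `g_p`, `zeta_p`, `g_a`, `zeta_a` (may be empty);
#'   `NULL` disables the two-body Jastrow
#' @param jastrow_basis list of [basis_function()] for the three/four-body
#'   term (`NULL` disables it)
#' @param gamma symmetric Q_J x Q_J coefficient matrix of the three-body
#'   term
#' @param A symmetric positive-definite 3 N_Q x 3 N_Q drudon matrix;
#'   default `mu_i omega_i` on the diagonal (exact for isolated QDOs)
#' @param B 3 x 3 N_Q electron-drudon coupling matrix; default zero
#' @return object of class `ansatz_parameters`
#' @export
ansatz_parameters <- function(system, mo = NULL, jastrow_pair = NULL,
                              jastrow_basis = NULL, gamma = NULL,
                              A = NULL, B = NULL) {
  ne <- n_electrons(system); nq <- n_qdos(system)
  if (ne > 0) {
    if (is.null(mo)) stop("ansatz_parameters: electrons need orbitals")
    if (ncol(mo$coefficients) < max(system$n_up, system$n_down)) {
      stop("ansatz_parameters: fewer orbitals than occupied spin states")
    }
  }
  if (!is.null(jastrow_pair)) {
    jp <- jastrow_pair
    jp$b_p <- if (is.null(jp$b_p)) 1 else jp$b_p
    jp$b_a <- if (is.null(jp$b_a)) 1 else jp$b_a
    for (f in c("g_p", "zeta_p", "g_a", "zeta_a")) {
      if (is.null(jp[[f]])) jp[[f]] <- numeric(0)
    }
    if (length(jp$g_p) != length(jp$zeta_p) ||
        length(jp$g_a) != length(jp$zeta_a)) {
      stop("ansatz_parameters: g and zeta lengths differ")
    }
    if (any(c(jp$zeta_p, jp$zeta_a) <= 0)) {
      stop("ansatz_parameters: Jastrow exponents must be > 0")
    }
    jastrow_pair <- jp
  }
  if (!is.null(jastrow_basis)) {
    qj <- length(jastrow_basis)
    if (is.null(gamma)) gamma <- matrix(0, qj, qj)
    gamma <- as.matrix(gamma)
    if (!isTRUE(all.equal(gamma, t(gamma), tolerance = 1e-12))) {
      stop("ansatz_parameters: gamma must be symmetric")
    }
    if (nrow(gamma) != qj) stop("ansatz_parameters: gamma/basis size clash")
  } else {
    gamma <- NULL
  }
  if (nq > 0) {
    if (is.null(A)) A <- diag(rep(system$mu * system$omega, each = 3),
                              3 * nq)
    A <- as.matrix(A)
    if (!isTRUE(all.equal(A, t(A), tolerance = 1e-10))) {
      stop("ansatz_parameters: A must be symmetric")
    }
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("ansatz_parameters: A must be positive definite")
    if (is.null(B)) B <- matrix(0, 3, 3 * nq)
    B <- as.matrix(B)
    stopifnot(nrow(B) == 3, ncol(B) == 3 * nq)
  } else {
    A <- NULL; B <- NULL
  }
  structure(list(mo = mo, jastrow_pair = jastrow_pair,
                 jastrow_basis = jastrow_basis, gamma = gamma,
                 A = A, B = B),
            class = "ansatz_parameters")
}

# ---- two-body Jastrow pair function --------------------------------------
# u(r) = c r/(1+br) + sum_n g_n exp(-zeta_n r^2)
# c = 1/4 parallel, 1/2 antiparallel (Kato cusp conditions)
u_pair <- function(r, b, g, zeta, cusp) {
  v <- cusp * r / (1 + b * r)
  for (n in seq_along(g)) v <- v + g[n] * exp(-zeta[n] * r^2)
  v
}
u_pair_d1 <- function(r, b, g, zeta, cusp) {
  v <- cusp / (1 + b * r)^2
  for (n in seq_along(g)) v <- v - 2 * zeta[n] * g[n] * r * exp(-zeta[n] * r^2)
  v
}
u_pair_d2 <- function(r, b, g, zeta, cusp) {
  v <- -2 * b * cusp / (1 + b * r)^3
  for (n in seq_along(g)) {
    v <- v + g[n] * (4 * zeta[n]^2 * r^2 - 2 * zeta[n]) * exp(-zeta[n] * r^2)
  }
  v
}

CUSP_PARALLEL <- 0.25
CUSP_ANTIPARALLEL <- 0.5

# spin of electron i (1..n_up are up)
pair_is_parallel <- function(system, i, j) {
  (i <= system$n_up) == (j <= system$n_up)
}

# ---- batched factor evaluations ------------------------------------------
# All take Xe (nw x N_e x 3) / Xd (nw x N_Q x 3) and return value plus,
# when derivs = TRUE, per-particle gradient and Laplacian contributions of
# log Psi. Particle indexing: electrons 1..N_e then drudons.

wf_slater_batch <- function(params, system, Xe, derivs = FALSE) {
  ne <- n_electrons(system)
  nw <- dim(Xe)[1]
  logabs <- numeric(nw); sgn <- rep(1, nw)
  grad <- if (derivs) array(0, c(nw, ne, 3)) else NULL
  lap <- if (derivs) matrix(0, nw, ne) else NULL
  for (spin in c("up", "down")) {
    n <- if (spin == "up") system$n_up else system$n_down
    if (n == 0) next
    idx <- if (spin == "up") seq_len(n) else system$n_up + seq_len(n)
    # flatten electron block across walkers for one basis pass
    Rs <- matrix(0, nw * n, 3)
    for (k in seq_len(n)) Rs[(k - 1) * nw + seq_len(nw), ] <- mslice(Xe, idx[k])
    em <- eval_mos(params$mo, Rs)
    no <- ncol(params$mo$coefficients)
    if (n == 1L) {
      v <- em$val[, 1]
      logabs <- logabs + log(pmax(abs(v), 1e-300))
      sgn <- sgn * sign(v)
      sgn[v == 0] <- 0
      if (derivs) {
        g <- em$grad[, 1, , drop = FALSE]; dim(g) <- c(nw, 3)
        gl <- g / v
        grad[, idx[1], ] <- grad[, idx[1], ] + gl
        lap[, idx[1]] <- lap[, idx[1]] + em$lap[, 1] / v - rowSums(gl * gl)
      }
    } else {
      for (w in seq_len(nw)) {
        S <- matrix(0, n, n)
        for (k in seq_len(n)) S[k, ] <- em$val[(k - 1) * nw + w, seq_len(n)]
        dd <- determinant(S, logarithm = TRUE)
        if (!is.finite(dd$modulus) || abs(dd$modulus) > 690) {
          # singular (node) or overflow-guard
          if (!is.finite(dd$modulus) || dd$modulus < -690) {
            logabs[w] <- -Inf; sgn[w] <- 0
            next
          }
        }
        logabs[w] <- logabs[w] + as.numeric(dd$modulus)
        sgn[w] <- sgn[w] * as.numeric(dd$sign)
        if (derivs && is.finite(logabs[w])) {
          invS <- tryCatch(solve(S), error = function(e) NULL)
          if (is.null(invS)) { logabs[w] <- -Inf; sgn[w] <- 0; next }
          for (k in seq_len(n)) {
            row <- (k - 1) * nw + w
            gk <- numeric(3); lk <- 0
            for (i in seq_len(n)) {
              gk <- gk + invS[i, k] * em$grad[row, i, ]
              lk <- lk + invS[i, k] * em$lap[row, i]
            }
            grad[w, idx[k], ] <- grad[w, idx[k], ] + gk
            lap[w, idx[k]] <- lap[w, idx[k]] + lk - sum(gk * gk)
          }
        }
      }
    }
  }
  list(log = logabs, sign = sgn, grad = grad, lap = lap)
}

wf_j2_batch <- function(params, system, Xe, derivs = FALSE) {
  jp <- params$jastrow_pair
  ne <- n_electrons(system)
  nw <- dim(Xe)[1]
  val <- numeric(nw)
  grad <- if (derivs) array(0, c(nw, ne, 3)) else NULL
  lap <- if (derivs) matrix(0, nw, ne) else NULL
  if (is.null(jp) || ne < 2) {
    return(list(log = val, grad = grad, lap = lap))
  }
  for (i in 1:(ne - 1)) for (j in (i + 1):ne) {
    par <- pair_is_parallel(system, i, j)
    b <- if (par) jp$b_p else jp$b_a
    g <- if (par) jp$g_p else jp$g_a
    z <- if (par) jp$zeta_p else jp$zeta_a
    cusp <- if (par) CUSP_PARALLEL else CUSP_ANTIPARALLEL
    dij <- mslice(Xe, i) - mslice(Xe, j)
    r <- pmax(sqrt(rowSums(dij * dij)), 1e-12)
    val <- val + u_pair(r, b, g, z, cusp)
    if (derivs) {
      d1 <- u_pair_d1(r, b, g, z, cusp)
      d2 <- u_pair_d2(r, b, g, z, cusp)
      gv <- dij * (d1 / r)
      grad[, i, ] <- grad[, i, ] + gv
      grad[, j, ] <- grad[, j, ] - gv
      lp <- d2 + 2 * d1 / r
      lap[, i] <- lap[, i] + lp
      lap[, j] <- lap[, j] + lp
    }
  }
  list(log = val, grad = grad, lap = lap)
}

# per-electron Jastrow basis projections: list of val (nw x Q),
# grad (nw x Q x 3), lap (nw x Q)
j3_projections <- function(params, Xe, derivs) {
  ne <- dim(Xe)[2]; nw <- dim(Xe)[1]
  qj <- length(params$jastrow_basis)
  V <- vector("list", ne); G <- vector("list", ne); L <- vector("list", ne)
  for (i in seq_len(ne)) {
    vi <- matrix(0, nw, qj)
    gi <- if (derivs) array(0, c(nw, qj, 3)) else NULL
    li <- if (derivs) matrix(0, nw, qj) else NULL
    Ri <- mslice(Xe, i)
    for (q in seq_len(qj)) {
      e <- eval_basis(params$jastrow_basis[[q]], Ri)
      vi[, q] <- e$val
      if (derivs) { gi[, q, ] <- e$grad; li[, q] <- e$lap }
    }
    V[[i]] <- vi; G[[i]] <- gi; L[[i]] <- li
  }
  list(V = V, G = G, L = L)
}

wf_j3_batch <- function(params, system, Xe, derivs = FALSE, proj = NULL) {
  ne <- n_electrons(system)
  nw <- dim(Xe)[1]
  val <- numeric(nw)
  grad <- if (derivs) array(0, c(nw, ne, 3)) else NULL
  lap <- if (derivs) matrix(0, nw, ne) else NULL
  if (is.null(params$jastrow_basis) || ne < 2) {
    return(list(log = val, grad = grad, lap = lap))
  }
  if (is.null(proj)) proj <- j3_projections(params, Xe, derivs)
  V <- proj$V
  gam <- params$gamma
  # precompute per-electron projections W_i = V_i gamma, then accumulate
  # the i<j pair sum: O(N_e^2) multiplications over precomputed vectors
  W <- lapply(V, function(v) v %*% gam)
  for (i in 1:(ne - 1)) for (j in (i + 1):ne) {
    val <- val + rowSums(W[[i]] * V[[j]])
  }
  if (derivs) {
    S <- Reduce(`+`, V)                  # sum over electrons of chi(r_i)
    for (k in seq_len(ne)) {
      tk <- (S - V[[k]]) %*% gam         # gamma-projected field of others
      for (c3 in 1:3) {
        gk <- proj$G[[k]][, , c3, drop = FALSE]; dim(gk) <- c(nw, ncol(S))
        grad[, k, c3] <- rowSums(gk * tk)
      }
      lap[, k] <- rowSums(proj$L[[k]] * tk)
    }
  }
  list(log = val, grad = grad, lap = lap)
}

# stacked drudon displacements: nw x 3N_Q (drudon-major: d1x d1y d1z d2x ...)
drudon_displacements <- function(system, Xd) {
  nq <- n_qdos(system); nw <- dim(Xd)[1]
  D <- matrix(0, nw, 3 * nq)
  for (i in seq_len(nq)) {
    D[, 3 * (i - 1) + 1:3] <- sweep(mslice(Xd, i), 2, system$Rc[i, ])
  }
  D
}

wf_drudon_batch <- function(params, system, Xd, derivs = FALSE,
                            D = NULL) {
  nq <- n_qdos(system); nw <- dim(Xd)[1]
  if (is.null(D)) D <- drudon_displacements(system, Xd)
  DA <- D %*% params$A
  val <- -0.5 * rowSums(DA * D)
  grad <- NULL; lap <- NULL
  if (derivs) {
    grad <- array(0, c(nw, nq, 3))
    lap <- matrix(0, nw, nq)
    dA <- diag(params$A)
    for (i in seq_len(nq)) {
      blk <- 3 * (i - 1) + 1:3
      grad[, i, ] <- -DA[, blk]
      lap[, i] <- -sum(dA[blk])
    }
  }
  list(log = val, grad = grad, lap = lap)
}

# electronic dipole moment mu = sum_i Z_i R_i - sum_j r_j, batched (nw x 3)
electronic_dipole <- function(system, Xe) {
  nw <- dim(Xe)[1]
  mu <- matrix(0, nw, 3)
  if (length(system$Zn) > 0) {
    mu <- matrix(colSums(system$Rn * system$Zn), nw, 3, byrow = TRUE)
  }
  for (j in seq_len(n_electrons(system))) mu <- mu - mslice(Xe, j)
  mu
}

wf_coupling_batch <- function(params, system, Xe, Xd, derivs = FALSE,
                              D = NULL) {
  ne <- n_electrons(system); nq <- n_qdos(system)
  nw <- dim(Xd)[1]
  if (is.null(D)) D <- drudon_displacements(system, Xd)
  mu <- electronic_dipole(system, Xe)
  muB <- mu %*% params$B                 # nw x 3N_Q
  val <- rowSums(muB * D)
  egrad <- NULL; dgrad <- NULL
  if (derivs) {
    Bd <- D %*% t(params$B)              # nw x 3; gradient wrt any electron
    egrad <- -Bd
    dgrad <- array(0, c(nw, nq, 3))
    for (i in seq_len(nq)) dgrad[, i, ] <- muB[, 3 * (i - 1) + 1:3]
  }
  list(log = val, egrad = egrad, dgrad = dgrad)
}

# ---- full wave function ---------------------------------------------------

# batched log |Psi| (+ sign); Xe/Xd may be NULL for pure systems
psi_log_batch <- function(params, system, Xe, Xd) {
  ne <- n_electrons(system); nq <- n_qdos(system)
  nw <- if (ne > 0) dim(Xe)[1] else dim(Xd)[1]
  logv <- numeric(nw); sgn <- rep(1, nw)
  if (ne > 0) {
    sl <- wf_slater_batch(params, system, Xe)
    logv <- logv + sl$log; sgn <- sgn * sl$sign
    logv <- logv + wf_j2_batch(params, system, Xe)$log
    logv <- logv + wf_j3_batch(params, system, Xe)$log
  }
  if (nq > 0) {
    D <- drudon_displacements(system, Xd)
    logv <- logv + wf_drudon_batch(params, system, Xd, D = D)$log
    if (ne > 0) {
      logv <- logv + wf_coupling_batch(params, system, Xe, Xd, D = D)$log
    }
  }
  list(log = logv, sign = sgn)
}

# batched value + per-particle gradient/Laplacian of log|Psi|
psi_derivs_batch <- function(params, system, Xe, Xd) {
  ne <- n_electrons(system); nq <- n_qdos(system)
  nw <- if (ne > 0) dim(Xe)[1] else dim(Xd)[1]
  np <- ne + nq
  logv <- numeric(nw); sgn <- rep(1, nw)
  grad <- array(0, c(nw, np, 3)); lap <- matrix(0, nw, np)
  add_grad <- function(idx, g) {
    dim(g) <- c(nw, length(idx), 3)
    grad[, idx, ] <<- grad[, idx, , drop = FALSE] + g
  }
  add_lap <- function(idx, l) {
    lap[, idx] <<- lap[, idx, drop = FALSE] + matrix(l, nw, length(idx))
  }
  if (ne > 0) {
    sl <- wf_slater_batch(params, system, Xe, derivs = TRUE)
    logv <- logv + sl$log; sgn <- sgn * sl$sign
    add_grad(seq_len(ne), sl$grad); add_lap(seq_len(ne), sl$lap)
    j2 <- wf_j2_batch(params, system, Xe, derivs = TRUE)
    logv <- logv + j2$log
    if (!is.null(j2$grad)) {
      add_grad(seq_len(ne), j2$grad); add_lap(seq_len(ne), j2$lap)
    }
    j3 <- wf_j3_batch(params, system, Xe, derivs = TRUE)
    logv <- logv + j3$log
    if (!is.null(j3$grad)) {
      add_grad(seq_len(ne), j3$grad); add_lap(seq_len(ne), j3$lap)
    }
  }
  if (nq > 0) {
    D <- drudon_displacements(system, Xd)
    dr <- wf_drudon_batch(params, system, Xd, derivs = TRUE, D = D)
    logv <- logv + dr$log
    add_grad(ne + seq_len(nq), dr$grad); add_lap(ne + seq_len(nq), dr$lap)
    if (ne > 0) {
      cp <- wf_coupling_batch(params, system, Xe, Xd, derivs = TRUE, D = D)
      logv <- logv + cp$log
      for (k in seq_len(ne)) add_grad(k, cp$egrad)
      add_grad(ne + seq_len(nq), cp$dgrad)
      # coupling is bilinear: zero Laplacian per particle
    }
  }
  list(log = logv, sign = sgn, grad = grad, lap = lap)
}

# batched local energy: -sum_p (1/2m_p)(lap_p + |grad_p|^2) + V
local_energy_batch <- function(params, system, Xe, Xd, derivs = NULL) {
  if (is.null(derivs)) derivs <- psi_derivs_batch(params, system, Xe, Xd)
  masses <- particle_masses(system)
  nw <- length(derivs$log)
  kin <- numeric(nw)
  for (p in seq_along(masses)) {
    g <- derivs$grad[, p, , drop = FALSE]; dim(g) <- c(nw, 3)
    kin <- kin - (derivs$lap[, p] + rowSums(g * g)) / (2 * masses[p])
  }
  kin + potential_energy_batch(system, Xe, Xd)
}

# scalar walker -> batch-of-1 arrays
walker_to_batch <- function(walker) {
  ne <- nrow(walker$electrons); nq <- nrow(walker$drudons)
  Xe <- if (ne > 0) {
    aperm(array(t(walker$electrons), c(3, ne, 1)), c(3, 2, 1))
  } else NULL
  Xd <- if (nq > 0) {
    aperm(array(t(walker$drudons), c(3, nq, 1)), c(3, 2, 1))
  } else NULL
  list(Xe = Xe, Xd = Xd)
}

#' Log magnitude and sign of the trial wave function
#'
#' @param params an [ansatz_parameters()]
#' @param system an [el_qdo_system()]
#' @param walker a [walker_configuration()]
#' @return list with `log` (log |Psi|; `-Inf` at a node), `sign` (sign of
#'   the determinant product; 0 at a node) and `node` flag
#' @export
log_abs_psi <- function(params, system, walker) {
  check_walker(system, walker)
  b <- walker_to_batch(walker)
  r <- psi_log_batch(params, system, b$Xe, b$Xd)
  list(log = r$log, sign = r$sign, node = !is.finite(r$log) | r$sign == 0)
}

#' Slater determinant factor of the electronic wave function
#'
#' Product of the spin-up and spin-down determinants of occupied molecular
#' orbitals; an empty spin channel contributes a factor 1.
#'
#' @param params an [ansatz_parameters()] (only `mo` is used)
#' @param up n_up x 3 matrix of spin-up electron positions (bohr)
#' @param down n_down x 3 matrix of spin-down positions
#' @return determinant product (value, not log)
#' @export
slater_factor <- function(params, up = matrix(0, 0, 3),
                          down = matrix(0, 0, 3)) {
  one <- function(R) {
    R <- rbind(matrix(0, 0, 3), as.matrix(R))
    n <- nrow(R)
    if (n == 0) return(1)
    if (ncol(params$mo$coefficients) < n) {
      stop("slater_factor: more occupied orbitals than coefficients")
    }
    v <- eval_mos(params$mo, R)$val[, seq_len(n), drop = FALSE]
    det(v)
  }
  one(up) * one(down)
}

#' Two-body Jastrow log-factor
#'
#' Sum over electron pairs of u(r) = c r/(1+br) + sum_n g_n exp(-zeta_n
#' r^2) with c = 1/4 (parallel spins) or 1/2 (antiparallel), the Kato cusp
#' values.
#'
#' @param params an [ansatz_parameters()]
#' @param electrons N_e x 3 matrix (bohr)
#' @param n_up electrons 1..n_up are spin-up
#' @return log-factor (scalar)
#' @export
jastrow_two_body <- function(params, electrons, n_up) {
  electrons <- as.matrix(electrons)
  sys <- list(n_up = as.integer(n_up),
              n_down = nrow(electrons) - as.integer(n_up))
  ne <- nrow(electrons)
  if (ne < 2 || is.null(params$jastrow_pair)) return(0)
  Xe <- aperm(array(t(electrons), c(3, ne, 1)), c(3, 2, 1))
  fake <- list(n_up = sys$n_up, n_down = sys$n_down)
  wf_j2_batch(params, fake, Xe)$log
}

#' Three/four-body Jastrow log-factor
#'
#' sum_{i<j} sum_{qp} gamma_qp chi_q(r_i) chi_p(r_j), accumulated from
#' precomputed per-electron basis projections (O(N_e^2) multiplications).
#'
#' @param params an [ansatz_parameters()] with `jastrow_basis` and `gamma`
#' @param electrons N_e x 3 matrix (bohr)
#' @return log-factor (scalar)
#' @export
jastrow_three_body <- function(params, electrons) {
  electrons <- as.matrix(electrons)
  ne <- nrow(electrons)
  if (ne < 2 || is.null(params$jastrow_basis)) return(0)
  qj <- length(params$jastrow_basis)
  V <- matrix(0, ne, qj)
  x <- electrons[, 1]; y <- electrons[, 2]; z <- electrons[, 3]
  for (q in seq_len(qj)) {
    bf <- params$jastrow_basis[[q]]
    dx <- x - bf$center[1]; dy <- y - bf$center[2]; dz <- z - bf$center[3]
    s2 <- dx * dx + dy * dy + dz * dz
    if (bf$type == "sto") {
      V[, q] <- bf$coefficients[1] * exp(-bf$exponents[1] * sqrt(s2))
      next
    }
    v <- 0
    for (k in seq_along(bf$exponents)) {
      v <- v + bf$coefficients[k] * exp(-bf$exponents[k] * s2)
    }
    if (any(bf$l > 0L)) {
      v <- v * powsafe(dx, bf$l[1]) * powsafe(dy, bf$l[2]) *
        powsafe(dz, bf$l[3])
    }
    V[, q] <- v
  }
  W <- V %*% params$gamma      # per-electron projections, computed once
  acc <- 0
  for (i in seq_len(ne - 1)) {
    for (j in (i + 1):ne) {    # O(N_e^2) vector-vector multiplications
      acc <- acc + crossprod(W[i, ], V[j, ])[1L]
    }
  }
  acc
}

#' Drudonic Gaussian log-factor
#'
#' -1/2 d' A d over the stacked displacements d of all drudons from their
#' centers.
#'
#' @param params an [ansatz_parameters()]
#' @param system an [el_qdo_system()]
#' @param drudons N_Q x 3 matrix (bohr)
#' @return log Psi_Q (scalar)
#' @export
drudon_factor <- function(params, system, drudons) {
  drudons <- as.matrix(drudons)
  nq <- nrow(drudons)
  Xd <- aperm(array(t(drudons), c(3, nq, 1)), c(3, 2, 1))
  wf_drudon_batch(params, system, Xd)$log
}

#' Electron-drudon coupling log-factor
#'
#' mu(r_e)' B d with mu the electronic dipole moment (nuclear-charge
#' weighted origin) and d the stacked drudon displacements.
#'
#' @inheritParams drudon_factor
#' @param electrons N_e x 3 matrix (bohr)
#' @return log J_eQ (scalar)
#' @export
coupling_factor <- function(params, system, electrons, drudons) {
  electrons <- rbind(matrix(0, 0, 3), as.matrix(electrons))
  drudons <- as.matrix(drudons)
  ne <- nrow(electrons); nq <- nrow(drudons)
  Xe <- if (ne > 0) aperm(array(t(electrons), c(3, ne, 1)), c(3, 2, 1)) else
    array(0, c(1, 0, 3))
  Xd <- aperm(array(t(drudons), c(3, nq, 1)), c(3, 2, 1))
  wf_coupling_batch(params, system, Xe, Xd)$log
}

#' Local energy of a walker configuration
#'
#' H Psi / Psi at the configuration: kinetic terms assembled from
#' per-particle log-derivatives (grad^2 log Psi + |grad log Psi|^2) plus the
#' potential. Constant (zero-variance) for an exact eigenstate.
#'
#' @inheritParams log_abs_psi
#' @return local energy, hartree; `NaN` with a warning at a node
#' @export
local_energy <- function(params, system, walker) {
  check_walker(system, walker)
  b <- walker_to_batch(walker)
  d <- psi_derivs_batch(params, system, b$Xe, b$Xd)
  if (!is.finite(d$log)) {
    warning("local_energy: evaluated at a node")
    return(NaN)
  }
  local_energy_batch(params, system, b$Xe, b$Xd, derivs = d)
}

# ---- parameter derivatives ------------------------------------------------

# ordered description of the optimizable parameter vector
param_map <- function(params) {
  map <- list()
  add <- function(name, length) {
    map[[length(map) + 1L]] <<- list(name = name, length = length)
  }
  jp <- params$jastrow_pair
  if (!is.null(jp)) {
    add("b_p", 1); add("b_a", 1)
    if (length(jp$g_p)) { add("g_p", length(jp$g_p)); add("zeta_p", length(jp$zeta_p)) }
    if (length(jp$g_a)) { add("g_a", length(jp$g_a)); add("zeta_a", length(jp$zeta_a)) }
  }
  if (!is.null(params$gamma)) {
    q <- nrow(params$gamma)
    add("gamma", q * (q + 1) / 2)
  }
  if (!is.null(params$A)) {
    m <- nrow(params$A)
    add("A", m * (m + 1) / 2)
    add("B", 3 * m)
  }
  map
}

# total length of the optimizable vector
param_length <- function(params) {
  sum(vapply(param_map(params), `[[`, 0, "length"))
}

# flatten the optimizable parameters into a numeric vector (upper triangles
# of symmetric matrices stored column-major, diagonal included)
params_to_vector <- function(params) {
  out <- numeric(0)
  jp <- params$jastrow_pair
  if (!is.null(jp)) {
    out <- c(out, jp$b_p, jp$b_a)
    if (length(jp$g_p)) out <- c(out, jp$g_p, jp$zeta_p)
    if (length(jp$g_a)) out <- c(out, jp$g_a, jp$zeta_a)
  }
  if (!is.null(params$gamma)) {
    out <- c(out, params$gamma[upper.tri(params$gamma, diag = TRUE)])
  }
  if (!is.null(params$A)) {
    out <- c(out, params$A[upper.tri(params$A, diag = TRUE)], as.numeric(params$B))
  }
  out
}

# inverse of params_to_vector
vector_to_params <- function(params, v) {
  i <- 0
  take <- function(n) { out <- v[i + seq_len(n)]; i <<- i + n; out }
  jp <- params$jastrow_pair
  if (!is.null(jp)) {
    jp$b_p <- take(1); jp$b_a <- take(1)
    if (length(jp$g_p)) { jp$g_p <- take(length(jp$g_p)); jp$zeta_p <- take(length(jp$zeta_p)) }
    if (length(jp$g_a)) { jp$g_a <- take(length(jp$g_a)); jp$zeta_a <- take(length(jp$zeta_a)) }
    params$jastrow_pair <- jp
  }
  if (!is.null(params$gamma)) {
    q <- nrow(params$gamma)
    g <- matrix(0, q, q)
    g[upper.tri(g, diag = TRUE)] <- take(q * (q + 1) / 2)
    g <- g + t(g) - diag(diag(g))
    params$gamma <- g
  }
  if (!is.null(params$A)) {
    m <- nrow(params$A)
    A <- matrix(0, m, m)
    A[upper.tri(A, diag = TRUE)] <- take(m * (m + 1) / 2)
    A <- A + t(A) - diag(diag(A))
    params$A <- A
    params$B <- matrix(take(3 * m), 3, m)
  }
  params
}

# batched O_k = d log|Psi| / d p_k: returns nw x K matrix
logderiv_batch <- function(params, system, Xe, Xd) {
  ne <- n_electrons(system); nq <- n_qdos(system)
  nw <- if (ne > 0) dim(Xe)[1] else dim(Xd)[1]
  cols <- list()
  jp <- params$jastrow_pair
  if (!is.null(jp)) {
    db_p <- numeric(nw); db_a <- numeric(nw)
    ngp <- length(jp$g_p); nga <- length(jp$g_a)
    dg_p <- matrix(0, nw, ngp); dz_p <- matrix(0, nw, ngp)
    dg_a <- matrix(0, nw, nga); dz_a <- matrix(0, nw, nga)
    if (ne >= 2) {
      for (i in 1:(ne - 1)) for (j in (i + 1):ne) {
        par <- pair_is_parallel(system, i, j)
        dij <- mslice(Xe, i) - mslice(Xe, j)
        r <- pmax(sqrt(rowSums(dij * dij)), 1e-12)
        if (par) {
          db_p <- db_p - CUSP_PARALLEL * r^2 / (1 + jp$b_p * r)^2
          for (n in seq_len(ngp)) {
            e <- exp(-jp$zeta_p[n] * r^2)
            dg_p[, n] <- dg_p[, n] + e
            dz_p[, n] <- dz_p[, n] - jp$g_p[n] * r^2 * e
          }
        } else {
          db_a <- db_a - CUSP_ANTIPARALLEL * r^2 / (1 + jp$b_a * r)^2
          for (n in seq_len(nga)) {
            e <- exp(-jp$zeta_a[n] * r^2)
            dg_a[, n] <- dg_a[, n] + e
            dz_a[, n] <- dz_a[, n] - jp$g_a[n] * r^2 * e
          }
        }
      }
    }
    cols <- c(cols, list(db_p, db_a))
    if (ngp) cols <- c(cols, list(dg_p, dz_p))
    if (nga) cols <- c(cols, list(dg_a, dz_a))
  }
  if (!is.null(params$gamma)) {
    q <- nrow(params$gamma)
    M <- array(0, c(nw, q, q))        # sum_{i<j} (v_i v_j' + v_j v_i')
    if (ne >= 2) {
      proj <- j3_projections(params, Xe, derivs = FALSE)
      S <- Reduce(`+`, proj$V)
      SS <- array(0, c(nw, q, q)); VV <- array(0, c(nw, q, q))
      for (a in seq_len(q)) for (b2 in seq_len(q)) {
        SS[, a, b2] <- S[, a] * S[, b2]
        for (i in seq_len(ne)) {
          VV[, a, b2] <- VV[, a, b2] + proj$V[[i]][, a] * proj$V[[i]][, b2]
        }
      }
      M <- SS - VV
    }
    dgam <- matrix(0, nw, q * (q + 1) / 2)
    k <- 0
    for (b2 in seq_len(q)) for (a in seq_len(b2)) {  # column-major upper tri
      k <- k + 1
      dgam[, k] <- if (a == b2) M[, a, a] / 2 else M[, a, b2]
    }
    cols <- c(cols, list(dgam))
  }
  if (!is.null(params$A)) {
    m <- nrow(params$A)
    D <- drudon_displacements(system, Xd)
    dA <- matrix(0, nw, m * (m + 1) / 2)
    k <- 0
    for (b2 in seq_len(m)) for (a in seq_len(b2)) {
      k <- k + 1
      dA[, k] <- if (a == b2) -0.5 * D[, a]^2 else -D[, a] * D[, b2]
    }
    mu <- if (ne > 0) electronic_dipole(system, Xe) else matrix(0, nw, 3)
    dB <- matrix(0, nw, 3 * m)
    for (b2 in seq_len(m)) for (a in 1:3) {
      dB[, (b2 - 1) * 3 + a] <- mu[, a] * D[, b2]
    }
    cols <- c(cols, list(dA, dB))
  }
  do.call(cbind, cols)
}

#' Logarithmic parameter derivatives of the trial wave function
#'
#' O_k = d log|Psi| / d p_k over the optimizable parameters (two-body
#' Jastrow cusps and remodulation, three-body gamma, drudon matrix A,
#' coupling matrix B); orbital coefficients are fixed and excluded.
#' Symmetric-matrix blocks count each off-diagonal entry once.
#'
#' @inheritParams log_abs_psi
#' @return named numeric vector
#' @export
parameter_log_derivatives <- function(params, system, walker) {
  check_walker(system, walker)
  b <- walker_to_batch(walker)
  v <- drop(logderiv_batch(params, system, b$Xe, b$Xd))
  names(v) <- param_names(params)
  v
}

param_names <- function(params) {
  out <- character(0)
  jp <- params$jastrow_pair
  if (!is.null(jp)) {
    out <- c(out, "b_p", "b_a")
    if (length(jp$g_p)) {
      out <- c(out, paste0("g_p", seq_along(jp$g_p)),
               paste0("zeta_p", seq_along(jp$zeta_p)))
    }
    if (length(jp$g_a)) {
      out <- c(out, paste0("g_a", seq_along(jp$g_a)),
               paste0("zeta_a", seq_along(jp$zeta_a)))
    }
  }
  if (!is.null(params$gamma)) {
    q <- nrow(params$gamma)
    for (b2 in seq_len(q)) for (a in seq_len(b2)) {
      out <- c(out, sprintf("gamma[%d,%d]", a, b2))
    }
  }
  if (!is.null(params$A)) {
    m <- nrow(params$A)
    for (b2 in seq_len(m)) for (a in seq_len(b2)) {
      out <- c(out, sprintf("A[%d,%d]", a, b2))
    }
    for (b2 in seq_len(m)) for (a in 1:3) {
      out <- c(out, sprintf("B[%d,%d]", a, b2))
    }
  }
  out
}
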