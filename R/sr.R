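#' Stochastic reconfiguration (SR) optimization of the ansatz
#'
#' Natural-gradient-like update of the wave-function parameters using the
#' covariance of the logarithmic parameter derivatives O_k over a sample of
#' configurations drawn from |Psi|^2:
#' S_kl = <O_k O_l> - <O_k><O_l>, g_k = 2 (<E_L O_k> - <E_L><O_k>),
#' delta p = -dt (S + eps I)^{-1} g.
#' Determinant (orbital) parameters are fixed throughout. The drudon matrix
#' A is projected back to symmetric positive definite (eigenvalue floor)
#' if an update breaks normalizability, and Jastrow exponents are floored
#' at a small positive value.
#'
#' @name stochastic_reconfiguration
NULL

# project a symmetric matrix to SPD with an eigenvalue floor
spd_project <- function(A, floor = 1e-6) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) >= floor) return(A)
  vals <- pmax(e$values, floor)
  e$vectors %*% (vals * t(e$vectors))
}

#' One SR parameter update from a sample of configurations
#'
#' @param params an [ansatz_parameters()]
#' @param system an [el_qdo_system()]
#' @param sample list with batched coordinate arrays `Xe`, `Xd` drawn from
#'   `|Psi_params|^2` (as produced by the VMC sampler)
#' @param learning_rate step size dt
#' @param epsilon diagonal regularization of S; doubled internally until
#'   the linear solve succeeds
#' @return list with `params` (updated), `energy` (sample mean local
#'   energy), `grad` (g vector), `delta` (parameter change), `epsilon`
#'   (regularization actually used)
#' @export
sr_step <- function(params, system, sample, learning_rate = 0.1,
                    epsilon = 1e-3) {
  O <- logderiv_batch(params, system, sample$Xe, sample$Xd)
  E <- local_energy_batch(params, system, sample$Xe, sample$Xd)
  keep <- is.finite(E) & apply(is.finite(O), 1, all)
  O <- O[keep, , drop = FALSE]; E <- E[keep]
  Obar <- colMeans(O)
  Oc <- sweep(O, 2, Obar)
  S <- crossprod(Oc) / nrow(O)
  g <- 2 * (colMeans(E * O) - mean(E) * Obar)
  dp <- NULL
  eps <- epsilon
  for (try in 1:12) {
    dp <- tryCatch(
      -learning_rate * solve(S + eps * diag(ncol(S)), g),
      error = function(e) NULL)
    if (!is.null(dp) && all(is.finite(dp))) break
    eps <- eps * 2
  }
  if (is.null(dp) || !all(is.finite(dp))) {
    stop("sr_step: overlap matrix irreparably ill-conditioned")
  }
  v <- params_to_vector(params) + dp
  new_params <- vector_to_params(params, v)
  # restore constraints the raw update may break
  if (!is.null(new_params$A)) new_params$A <- spd_project(new_params$A)
  jp <- new_params$jastrow_pair
  if (!is.null(jp)) {
    jp$b_p <- max(jp$b_p, 1e-3); jp$b_a <- max(jp$b_a, 1e-3)
    if (length(jp$zeta_p)) jp$zeta_p <- pmax(jp$zeta_p, 1e-4)
    if (length(jp$zeta_a)) jp$zeta_a <- pmax(jp$zeta_a, 1e-4)
    new_params$jastrow_pair <- jp
  }
  list(params = new_params, energy = mean(E), grad = g, delta = dp,
       epsilon = eps, S = S)
}

#' Correlated-sampling energy change and wave-function overlap proxy
#'
#' Reweights an existing sample from |Psi_old|^2 with w = |Psi_new /
#' Psi_old|^2 to estimate the energy change without resampling, and
#' returns the normalized overlap proxy <w>^2 / <w^2> in (0, 1]; the
#' optimizer resamples when the proxy drops below its threshold.
#'
#' @param params_old,params_new two [ansatz_parameters()]
#' @param system an [el_qdo_system()]
#' @param sample configurations drawn from `|Psi_old|^2`
#' @return list with `delta_energy`, `energy_new` (reweighted), `overlap`
#' @export
correlated_energy_delta <- function(params_old, params_new, system,
                                    sample) {
  lo <- psi_log_batch(params_old, system, sample$Xe, sample$Xd)$log
  ln <- psi_log_batch(params_new, system, sample$Xe, sample$Xd)$log
  lw <- 2 * (ln - lo)
  lw <- lw - max(lw[is.finite(lw)])
  w <- exp(lw)
  w[!is.finite(w)] <- 0
  if (all(w == 0)) stop("correlated_energy_delta: total loss of overlap")
  En <- local_energy_batch(params_new, system, sample$Xe, sample$Xd)
  Eo <- local_energy_batch(params_old, system, sample$Xe, sample$Xd)
  ok <- is.finite(En) & is.finite(Eo)
  w <- w[ok]; En <- En[ok]; Eo <- Eo[ok]
  energy_new <- sum(w * En) / sum(w)
  list(delta_energy = energy_new - mean(Eo),
       energy_new = energy_new,
       overlap = mean(w)^2 / mean(w^2))
}

#' SR optimization driver with correlated sampling
#'
#' Iterates [sr_step()], reusing the current sample between parameter
#' updates and resampling from the new wave function whenever the
#' correlated-sampling overlap proxy drops below `overlap_threshold`.
#'
#' @inheritParams sr_step
#' @param n_iter number of SR iterations
#' @param n_sample configurations per sample
#' @param overlap_threshold resample when <w>^2/<w^2> falls below this
#' @param learning_rate SR step size
#' @param seed RNG seed
#' @param verbose print per-iteration energies
#' @return list with `params` (final), `energies` (per-iteration sample
#'   means), `trace` (list of parameter vectors), `n_resamples`
#' @export
run_sr_optimization <- function(params, system, n_iter = 100,
                                n_sample = 2000, learning_rate = 0.1,
                                epsilon = 1e-3, overlap_threshold = 0.95,
                                seed = 1, verbose = FALSE) {
  set.seed(as.integer(seed))
  n_walkers <- min(200L, n_sample)
  n_collect <- ceiling(n_sample / n_walkers)
  smp <- sample_psi2(params, system, n_walkers, n_collect)
  deltas <- smp$deltas
  sample_params <- params     # wave function the current sample belongs to
  energies <- numeric(n_iter)
  trace <- vector("list", n_iter)
  n_res <- 0
  for (it in seq_len(n_iter)) {
    # reweight the sample if it was drawn from an older wave function
    st <- sr_step(params, system, smp, learning_rate, epsilon)
    energies[it] <- st$energy
    trace[[it]] <- params_to_vector(st$params)
    cor <- correlated_energy_delta(params, st$params, system, smp)
    params <- st$params
    if (cor$overlap < overlap_threshold) {
      smp <- sample_psi2(params, system, n_walkers, n_collect,
                         deltas = deltas, state = smp$state, n_equil = 10L)
      sample_params <- params
      n_res <- n_res + 1
    }
    if (verbose) {
      cat(sprintf("SR %3d  E = %.6f  overlap = %.3f\n",
                  it, st$energy, cor$overlap))
    }
  }
  list(params = params, energies = energies, trace = trace,
       n_resamples = n_res)
}
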