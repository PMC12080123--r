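#' VMC run settings
#'
#' @param delta_e,delta_d Gaussian move amplitudes (bohr) for electrons and
#'   drudons; a particle of mass m moves with amplitude delta/sqrt(m)
#' @param n_steps production sweeps (one proposed move per particle each)
#' @param n_walkers parallel walkers
#' @param n_tune_steps sweeps per amplitude-tuning window
#' @param n_equil equilibration sweeps before accumulation
#' @param seed RNG seed (one master stream per run; runs are reproducible
#'   given seed and n_walkers)
#' @param block_size initial block size for the blocking analysis
#' @return object of class `vmc_settings`
#' @export
vmc_settings <- function(delta_e = 1.0, delta_d = 1.0, n_steps = 500L,
                         n_walkers = 100L, n_tune_steps = 25L,
                         n_equil = 50L, seed = 1L, block_size = 1L) {
  stopifnot(delta_e > 0, delta_d > 0, n_steps >= 1, n_walkers >= 1,
            n_tune_steps >= 1, block_size >= 1)
  structure(list(delta_e = delta_e, delta_d = delta_d,
                 n_steps = as.integer(n_steps),
                 n_walkers = as.integer(n_walkers),
                 n_tune_steps = as.integer(n_tune_steps),
                 n_equil = as.integer(n_equil), seed = as.integer(seed),
                 block_size = as.integer(block_size)),
            class = "vmc_settings")
}

# per-particle move amplitudes: delta_e/sqrt(m_e) for electrons,
# delta_d/sqrt(mu_i) for drudons
move_amplitudes <- function(system, delta_e, delta_d) {
  c(rep(delta_e, n_electrons(system)), delta_d / sqrt(system$mu))
}

#' Propose a single-particle Metropolis move
#'
#' r' = r + Delta eta with eta standard normal and Delta = delta/sqrt(mass)
#' for the particle's species (mass scaling keeps the kinetic sampling
#' comparable across species). Uses the current R RNG stream.
#'
#' @param system an [el_qdo_system()]
#' @param particle particle index (electrons first, then drudons)
#' @param position current 3-vector
#' @param settings a [vmc_settings()]
#' @return trial 3-vector
#' @export
propose_move <- function(system, particle, position, settings) {
  amp <- move_amplitudes(system, settings$delta_e, settings$delta_d)[particle]
  position + amp * stats::rnorm(3)
}

# ---- batched walker state -------------------------------------------------

# initial population: electrons Gaussian around nuclei, drudons around
# centers
init_population <- function(system, n_walkers, spread = 0.7) {
  ne <- n_electrons(system); nq <- n_qdos(system)
  Xe <- if (ne > 0) {
    X <- array(0, c(n_walkers, ne, 3))
    nn <- length(system$Zn)
    for (j in seq_len(ne)) {
      at <- ((j - 1) %% nn) + 1
      X[, j, ] <- matrix(system$Rn[at, ], n_walkers, 3, byrow = TRUE) +
        spread * matrix(stats::rnorm(3 * n_walkers), n_walkers, 3)
    }
    X
  } else NULL
  Xd <- if (nq > 0) {
    X <- array(0, c(n_walkers, nq, 3))
    for (j in seq_len(nq)) {
      s <- 1 / sqrt(2 * system$mu[j] * system$omega[j])
      X[, j, ] <- matrix(system$Rc[j, ], n_walkers, 3, byrow = TRUE) +
        s * matrix(stats::rnorm(3 * n_walkers), n_walkers, 3)
    }
    X
  } else NULL
  list(Xe = Xe, Xd = Xd)
}

set_particle <- function(state, system, p, new) {
  ne <- n_electrons(system)
  if (p <= ne) state$Xe[, p, ] <- new else state$Xd[, p - ne, ] <- new
  state
}

get_particle <- function(state, system, p) {
  ne <- n_electrons(system)
  if (p <= ne) mslice(state$Xe, p) else mslice(state$Xd, p - ne)
}

# one Metropolis sweep over the whole population; returns updated state,
# cached log psi and per-species acceptance counts
sweep_population <- function(params, system, state, logpsi, amps) {
  ne <- n_electrons(system); nq <- n_qdos(system)
  nw <- if (ne > 0) dim(state$Xe)[1] else dim(state$Xd)[1]
  acc <- c(e = 0, d = 0); prop <- c(e = 0, d = 0)
  order_e <- if (ne > 0) sample(seq_len(ne)) else integer(0)
  order_d <- if (nq > 0) ne + sample(seq_len(nq)) else integer(0)
  for (p in c(order_e, order_d)) {
    species <- if (p <= ne) "e" else "d"
    cur <- get_particle(state, system, p)
    trial_state <- set_particle(state, system, p,
                                cur + amps[p] * matrix(stats::rnorm(3 * nw), nw, 3))
    lp_new <- psi_log_batch(params, system, trial_state$Xe, trial_state$Xd)$log
    lr <- 2 * (lp_new - logpsi)
    ok <- log(stats::runif(nw)) < lr
    ok[!is.finite(lp_new)] <- FALSE
    if (any(ok)) {
      newpos <- get_particle(trial_state, system, p)
      curpos <- cur
      curpos[ok, ] <- newpos[ok, ]
      state <- set_particle(state, system, p, curpos)
      logpsi[ok] <- lp_new[ok]
    }
    acc[species] <- acc[species] + sum(ok)
    prop[species] <- prop[species] + nw
  }
  list(state = state, logpsi = logpsi, accepted = acc, proposed = prop)
}

#' One Metropolis sweep over a single walker
#'
#' Each particle is proposed once (electrons first, then drudons, each
#' block in random order) and accepted with probability
#' min(1, |Psi'/Psi|^2).
#'
#' @param params an [ansatz_parameters()]
#' @param system an [el_qdo_system()]
#' @param walker a [walker_configuration()]
#' @param settings a [vmc_settings()]
#' @return list with `walker`, `accepted` and `proposed` counts per species
#' @export
metropolis_sweep <- function(params, system, walker, settings) {
  check_walker(system, walker)
  b <- walker_to_batch(walker)
  state <- list(Xe = b$Xe, Xd = b$Xd)
  lp <- psi_log_batch(params, system, state$Xe, state$Xd)$log
  if (!is.finite(lp)) stop("metropolis_sweep: walker starts on a node")
  amps <- move_amplitudes(system, settings$delta_e, settings$delta_d)
  r <- sweep_population(params, system, state, lp, amps)
  ne <- n_electrons(system); nq <- n_qdos(system)
  w <- walker_configuration(
    electrons = if (ne > 0) matrix(r$state$Xe[1, , ], ne, 3) else matrix(0, 0, 3),
    drudons = if (nq > 0) matrix(r$state$Xd[1, , ], nq, 3) else matrix(0, 0, 3),
    weight = walker$weight)
  list(walker = w, accepted = r$accepted, proposed = r$proposed)
}

#' Tune the Metropolis move amplitudes to 50% acceptance
#'
#' Multiplicative feedback delta <- delta * clip(acc/0.5, 0.5, 2) per
#' species over tuning windows until both species' acceptance is within
#' 50% +/- 2%.
#'
#' @inheritParams metropolis_sweep
#' @param state optional pre-equilibrated population (internal reuse)
#' @param max_windows feedback iterations before giving up (with a warning)
#' @return list with `delta_e`, `delta_d`, `acceptance` (per species),
#'   `converged`, and the final population `state` and `logpsi`
#' @export
tune_amplitudes <- function(params, system, settings, state = NULL,
                            max_windows = 60L) {
  ne <- n_electrons(system); nq <- n_qdos(system)
  if (is.null(state)) state <- init_population(system, settings$n_walkers)
  logpsi <- psi_log_batch(params, system, state$Xe, state$Xd)$log
  de <- settings$delta_e; dd <- settings$delta_d
  accs <- c(e = NA_real_, d = NA_real_)
  converged <- FALSE
  for (win in seq_len(max_windows)) {
    amps <- move_amplitudes(system, de, dd)
    acc <- c(e = 0, d = 0); prop <- c(e = 0, d = 0)
    for (s in seq_len(settings$n_tune_steps)) {
      r <- sweep_population(params, system, state, logpsi, amps)
      state <- r$state; logpsi <- r$logpsi
      acc <- acc + r$accepted; prop <- prop + r$proposed
    }
    accs <- ifelse(prop > 0, acc / prop, NA_real_)
    done <- TRUE
    if (ne > 0) {
      if (abs(accs["e"] - 0.5) > 0.02) {
        de <- de * min(2, max(0.5, accs["e"] / 0.5)); done <- FALSE
      }
    }
    if (nq > 0) {
      if (abs(accs["d"] - 0.5) > 0.02) {
        dd <- dd * min(2, max(0.5, accs["d"] / 0.5)); done <- FALSE
      }
    }
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("tune_amplitudes: did not converge; returning best amplitudes")
  }
  list(delta_e = de, delta_d = dd, acceptance = accs, converged = converged,
       state = state, logpsi = logpsi)
}

# ---- estimator machinery --------------------------------------------------

#' Energy estimate with blocked error bar
#'
#' @param mean mean energy (hartree)
#' @param stderr standard error (hartree), autocorrelation-corrected by
#'   blocking
#' @param variance variance of individual local-energy samples (hartree^2)
#' @param n_eff autocorrelation-adjusted effective number of samples
#' @param n_samples raw number of accumulated local energies
#' @return object of class `energy_estimate`
#' @export
energy_estimate <- function(mean, stderr, variance, n_eff, n_samples) {
  structure(list(mean = mean, stderr = stderr, variance = variance,
                 n_eff = n_eff, n_samples = n_samples),
            class = "energy_estimate")
}

#' @export
print.energy_estimate <- function(x, ...) {
  cat(sprintf("E = %.6f +/- %.6f hartree  (var %.3e, n_eff %.0f)\n",
              x$mean, x$stderr, x$variance, x$n_eff))
  invisible(x)
}

# blocking analysis on a time series of per-step means; returns the
# plateau stderr (maximum over block-size doublings with >= 8 blocks)
blocking_stderr <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2 || stats::var(x) == 0) return(list(stderr = 0, n_eff = n))
  best <- stats::sd(x) / sqrt(n)
  b <- 1
  while (n / (2 * b) >= 8) {
    b <- 2 * b
    nb <- floor(n / b)
    bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
    se <- stats::sd(bm) / sqrt(nb)
    if (se > best) best <- se
  }
  list(stderr = best,
       n_eff = if (best > 0) stats::var(x) / best^2 else n)
}

# build an energy_estimate from an (n_steps x n_walkers) local-energy
# matrix: per-step walker means form the blocked series; walkers at the
# same step are independent
estimate_from_samples <- function(E) {
  E <- as.matrix(E)
  nw <- ncol(E)
  series <- rowMeans(E)
  blk <- blocking_stderr(series)
  v <- stats::var(as.numeric(E))
  energy_estimate(mean = mean(series),
                  stderr = blk$stderr,   # series already averages walkers
                  variance = v,
                  n_eff = blk$n_eff * nw,
                  n_samples = length(E))
}

#' Run a variational Monte Carlo calculation
#'
#' Tunes the move amplitudes to 50% acceptance, equilibrates, and
#' accumulates blocked local-energy statistics over `n_steps` sweeps of
#' `n_walkers` walkers.
#'
#' @inheritParams metropolis_sweep
#' @param tune tune amplitudes before production (default TRUE)
#' @param keep_series keep the per-step energy series (for diagnostics)
#' @return an [energy_estimate()] with extra fields: `acceptance`
#'   (production acceptance per species), `delta_e`, `delta_d`, `settings`,
#'   and optionally `series`; the final population is attached as `state`
#' @export
run_vmc <- function(params, system, settings, tune = TRUE,
                    keep_series = FALSE) {
  set.seed(settings$seed)
  if (tune) {
    tn <- tune_amplitudes(params, system, settings)
    de <- tn$delta_e; dd <- tn$delta_d
    state <- tn$state; logpsi <- tn$logpsi
  } else {
    de <- settings$delta_e; dd <- settings$delta_d
    state <- init_population(system, settings$n_walkers)
    logpsi <- psi_log_batch(params, system, state$Xe, state$Xd)$log
  }
  if (all(!is.finite(logpsi))) stop("run_vmc: all walkers start on nodes")
  amps <- move_amplitudes(system, de, dd)
  for (s in seq_len(settings$n_equil)) {
    r <- sweep_population(params, system, state, logpsi, amps)
    state <- r$state; logpsi <- r$logpsi
  }
  nw <- settings$n_walkers
  E <- matrix(NA_real_, settings$n_steps, nw)
  acc <- c(e = 0, d = 0); prop <- c(e = 0, d = 0)
  for (s in seq_len(settings$n_steps)) {
    r <- sweep_population(params, system, state, logpsi, amps)
    state <- r$state; logpsi <- r$logpsi
    acc <- acc + r$accepted; prop <- prop + r$proposed
    E[s, ] <- local_energy_batch(params, system, state$Xe, state$Xd)
  }
  est <- estimate_from_samples(E)
  est$acceptance <- ifelse(prop > 0, acc / prop, NA_real_)
  est$delta_e <- de; est$delta_d <- dd
  est$settings <- settings
  if (keep_series) est$series <- rowMeans(E)
  est$state <- state
  est
}

# draw a decorrelated sample of configurations from |Psi|^2: returns
# stacked arrays plus cached local energies and log-derivatives
sample_psi2 <- function(params, system, n_walkers, n_collect,
                        n_decorr = 2L, deltas = NULL, state = NULL,
                        n_equil = 30L) {
  if (is.null(deltas)) {
    st <- vmc_settings(n_walkers = n_walkers, n_tune_steps = 10L)
    tn <- tune_amplitudes(params, system, st, state = state)
    deltas <- c(tn$delta_e, tn$delta_d)
    state <- tn$state
  } else if (is.null(state)) {
    state <- init_population(system, n_walkers)
  }
  logpsi <- psi_log_batch(params, system, state$Xe, state$Xd)$log
  amps <- move_amplitudes(system, deltas[1], deltas[2])
  for (s in seq_len(n_equil)) {
    r <- sweep_population(params, system, state, logpsi, amps)
    state <- r$state; logpsi <- r$logpsi
  }
  ne <- n_electrons(system); nq <- n_qdos(system)
  Xe_all <- if (ne > 0) array(0, c(n_walkers * n_collect, ne, 3)) else NULL
  Xd_all <- if (nq > 0) array(0, c(n_walkers * n_collect, nq, 3)) else NULL
  for (k in seq_len(n_collect)) {
    for (s in seq_len(n_decorr)) {
      r <- sweep_population(params, system, state, logpsi, amps)
      state <- r$state; logpsi <- r$logpsi
    }
    rows <- (k - 1) * n_walkers + seq_len(n_walkers)
    if (ne > 0) Xe_all[rows, , ] <- state$Xe
    if (nq > 0) Xd_all[rows, , ] <- state$Xd
  }
  list(Xe = Xe_all, Xd = Xd_all, deltas = deltas, state = state)
}

#' Measure the post-tuning Metropolis acceptance rate
#'
#' Tunes the move amplitudes to the 50% target, then measures the
#' single-particle acceptance fraction over at least `n_moves` production
#' moves with the tuned (frozen) amplitudes.
#'
#' @inheritParams metropolis_sweep
#' @param n_moves minimum number of single-particle moves to measure over
#' @return list with `acceptance` (overall fraction), `per_species`,
#'   `n_moves`, `delta_e`, `delta_d`
#' @export
measure_acceptance <- function(params, system, settings, n_moves = 1e5) {
  set.seed(settings$seed)
  tn <- tune_amplitudes(params, system, settings)
  state <- tn$state; logpsi <- tn$logpsi
  amps <- move_amplitudes(system, tn$delta_e, tn$delta_d)
  np <- n_quantum_particles(system)
  per_sweep <- np * settings$n_walkers
  n_sweeps <- ceiling(n_moves / per_sweep)
  acc <- c(e = 0, d = 0); prop <- c(e = 0, d = 0)
  for (s in seq_len(n_sweeps)) {
    r <- sweep_population(params, system, state, logpsi, amps)
    state <- r$state; logpsi <- r$logpsi
    acc <- acc + r$accepted; prop <- prop + r$proposed
  }
  list(acceptance = sum(acc) / sum(prop),
       per_species = ifelse(prop > 0, acc / prop, NA_real_),
       n_moves = sum(prop), delta_e = tn$delta_e, delta_d = tn$delta_d)
}
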