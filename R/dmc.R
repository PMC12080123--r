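#' DMC run settings
#'
#' @param dtau imaginary-time step, a.u. (default 0.005)
#' @param alpha_cut Zen-style local-energy cap parameter (default 0.2):
#'   deviations of E_L from the running estimate are clipped to
#'   +/- alpha sqrt(N/tau) with N the number of quantum particles
#' @param target_population walker population the comb rebalances to
#' @param n_blocks accumulation blocks
#' @param steps_per_block DMC steps per block
#' @param n_equil_blocks discarded equilibration blocks
#' @param seed RNG seed
#' @return object of class `dmc_settings`
#' @export
dmc_settings <- function(dtau = 0.005, alpha_cut = 0.2,
                         target_population = 100L, n_blocks = 50L,
                         steps_per_block = 50L, n_equil_blocks = 10L,
                         seed = 1L) {
  stopifnot(dtau > 0, alpha_cut > 0, target_population >= 10,
            n_blocks >= 1, steps_per_block >= 1)
  structure(list(dtau = dtau, alpha_cut = alpha_cut,
                 target_population = as.integer(target_population),
                 n_blocks = as.integer(n_blocks),
                 steps_per_block = as.integer(steps_per_block),
                 n_equil_blocks = as.integer(n_equil_blocks),
                 seed = as.integer(seed)),
            class = "dmc_settings")
}

#' Umrigar-rescaled drift velocity
#'
#' vbar = v (-1 + sqrt(1 + 2 |v|^2 tau)) / (|v|^2 tau): equals v for small
#' |v|^2 tau and saturates at magnitude sqrt(2/tau) for large |v|, taming
#' the drift divergence near the nodal surface.
#'
#' @param v n x 3 matrix (or 3-vector) of drift velocities grad log Psi
#' @param tau effective single-particle time step
#' @return rescaled velocities, same shape as `v`
#' @export
rescaled_drift <- function(v, tau) {
  vec <- is.null(dim(v))
  v <- matrix(v, ncol = 3)
  v2t <- rowSums(v * v) * tau
  f <- ifelse(v2t < 1e-12, 1 - v2t / 2, (-1 + sqrt(1 + 2 * v2t)) / v2t)
  out <- v * f
  if (vec) drop(out) else out
}

#' Capped local energy for DMC reweighting
#'
#' Hard clip of E_L - E_est to +/- alpha sqrt(N/tau); inactive when the
#' deviation is below the bound.
#'
#' @param E_L local energies (vector)
#' @param E_est current energy estimate
#' @param settings a [dmc_settings()]
#' @param n_particles number of quantum particles N
#' @param tau time step used in the bound (default `settings$dtau`)
#' @return capped local energies
#' @export
capped_local_energy <- function(E_L, E_est, settings, n_particles,
                                tau = settings$dtau) {
  bound <- settings$alpha_cut * sqrt(n_particles / tau)
  E_est + pmin(pmax(E_L - E_est, -bound), bound)
}

# systematic-comb resampling to n_target walkers; preserves total weight
comb_resample <- function(w, n_target) {
  W <- sum(w)
  u <- (stats::runif(1) + seq_len(n_target) - 1) / n_target
  idx <- findInterval(u * W, cumsum(w)) + 1L
  idx[idx > length(w)] <- length(w)
  list(idx = idx, weight = W / n_target)
}

# one propagation step of the whole population (particle-by-particle
# drift-diffusion with accept/reject); returns updated state and
# diagnostics
dmc_propagate <- function(params, system, state, derivs, settings) {
  ne <- n_electrons(system); nq <- n_qdos(system)
  np <- ne + nq
  nw <- length(derivs$log)
  masses <- particle_masses(system)
  disp_prop <- numeric(nw); disp_acc <- numeric(nw)
  n_acc <- 0; n_prop <- 0
  for (p in c(sample(seq_len(ne)), if (nq > 0) ne + sample(seq_len(nq)))) {
    tau_p <- settings$dtau / masses[p]
    x <- get_particle(state, system, p)
    g <- derivs$grad[, p, , drop = FALSE]; dim(g) <- c(nw, 3)
    vb <- rescaled_drift(g, tau_p)
    eta <- matrix(stats::rnorm(3 * nw), nw, 3)
    y <- x + vb * tau_p + sqrt(tau_p) * eta
    trial <- set_particle(state, system, p, y)
    dnew <- psi_derivs_batch(params, system, trial$Xe, trial$Xd)
    gy <- dnew$grad[, p, , drop = FALSE]; dim(gy) <- c(nw, 3)
    vby <- rescaled_drift(gy, tau_p)
    # log acceptance: |Psi|^2 ratio times reverse/forward Green's functions
    fwd <- y - x - vb * tau_p
    rev <- x - y - vby * tau_p
    logr <- 2 * (dnew$log - derivs$log) +
      (rowSums(fwd * fwd) - rowSums(rev * rev)) / (2 * tau_p)
    ok <- log(stats::runif(nw)) < logr
    ok[!is.finite(dnew$log)] <- FALSE
    if (p <= ne) ok[dnew$sign != derivs$sign] <- FALSE  # fixed node
    d2 <- rowSums((y - x)^2)
    disp_prop <- disp_prop + d2
    disp_acc <- disp_acc + ifelse(ok, d2, 0)
    n_prop <- n_prop + nw; n_acc <- n_acc + sum(ok)
    if (any(ok)) {
      xn <- x; xn[ok, ] <- y[ok, ]
      state <- set_particle(state, system, p, xn)
      # cached derivatives follow the accepted subpopulation
      derivs$log[ok] <- dnew$log[ok]
      derivs$sign[ok] <- dnew$sign[ok]
      derivs$grad[ok, , ] <- dnew$grad[ok, , ]
      derivs$lap[ok, ] <- dnew$lap[ok, ]
    }
  }
  ratio <- ifelse(disp_prop > 0, disp_acc / disp_prop, 1)
  list(state = state, derivs = derivs, tau_eff = settings$dtau * ratio,
       acceptance = n_acc / max(n_prop, 1))
}

#' Run a fixed-node diffusion Monte Carlo calculation
#'
#' Importance-sampled drift-diffusion of a weighted walker population with
#' Umrigar-rescaled drift, per-particle time steps dtau/m_i, accept/reject
#' against the importance-sampled Green's function, fixed-node constraint
#' on electron moves (the drudonic factor is nodeless), capped local-energy
#' reweighting, and a total-weight-preserving comb that rebalances the
#' population every step. The reported energy is the weighted mixed
#' estimator with blocked error bars.
#'
#' @param params an [ansatz_parameters()] (VMC-optimized recommended)
#' @param system an [el_qdo_system()]
#' @param settings a [dmc_settings()]
#' @param keep_series keep per-block energy/population series
#' @return an [energy_estimate()] with extra fields `acceptance`,
#'   `population` (final), `dtau`, `block_energies`, `cap_fraction`
#' @export
run_dmc <- function(params, system, settings, keep_series = FALSE) {
  set.seed(settings$seed)
  np <- n_quantum_particles(system)
  nw <- settings$target_population
  # VMC warm-up: tuned amplitudes + equilibrated population
  vst <- vmc_settings(n_walkers = nw, n_tune_steps = 10L)
  tn <- tune_amplitudes(params, system, vst)
  state <- tn$state
  amps <- move_amplitudes(system, tn$delta_e, tn$delta_d)
  logpsi <- tn$logpsi
  for (s in 1:20) {
    r <- sweep_population(params, system, state, logpsi, amps)
    state <- r$state; logpsi <- r$logpsi
  }
  derivs <- psi_derivs_batch(params, system, state$Xe, state$Xd)
  E_L <- local_energy_batch(params, system, state$Xe, state$Xd,
                            derivs = derivs)
  E_est <- mean(E_L[is.finite(E_L)])
  E_ref <- E_est
  w <- rep(1, nw)
  n_cap <- 0; n_elocal <- 0
  acc_sum <- 0; acc_n <- 0
  blocks <- numeric(settings$n_blocks)
  pops <- numeric(settings$n_blocks)
  s1 <- 0; s2 <- 0; sw <- 0   # raw local-energy moments (uncapped)
  total_blocks <- settings$n_equil_blocks + settings$n_blocks
  bound <- settings$alpha_cut * sqrt(np / settings$dtau)
  kept <- 0
  for (blk in seq_len(total_blocks)) {
    bsum <- 0; bw <- 0
    for (s in seq_len(settings$steps_per_block)) {
      E_old <- capped_local_energy(E_L, E_est, settings, np)
      pr <- dmc_propagate(params, system, state, derivs, settings)
      state <- pr$state; derivs <- pr$derivs
      acc_sum <- acc_sum + pr$acceptance; acc_n <- acc_n + 1
      E_L <- local_energy_batch(params, system, state$Xe, state$Xd,
                                derivs = derivs)
      n_cap <- n_cap + sum(abs(E_L - E_est) > bound, na.rm = TRUE)
      n_elocal <- n_elocal + length(E_L)
      E_new <- capped_local_energy(E_L, E_est, settings, np)
      w <- w * exp(-pr$tau_eff * (0.5 * (E_old + E_new) - E_ref))
      w[!is.finite(w)] <- 0
      W_tot <- sum(w)
      if (W_tot <= 0) stop("run_dmc: population collapsed (zero weight)")
      # per-step feedback pins the total weight to the target population
      E_ref <- E_est - log(W_tot / nw) / settings$dtau
      # mixed estimator accumulates before rebalancing
      bsum <- bsum + sum(w * E_L); bw <- bw + sum(w)
      if (blk > settings$n_equil_blocks) {
        s1 <- s1 + sum(w * E_L); s2 <- s2 + sum(w * E_L^2); sw <- sw + sum(w)
      }
      cr <- comb_resample(w, nw)
      state$Xe <- if (!is.null(state$Xe)) state$Xe[cr$idx, , , drop = FALSE]
      state$Xd <- if (!is.null(state$Xd)) state$Xd[cr$idx, , , drop = FALSE]
      derivs$log <- derivs$log[cr$idx]
      derivs$sign <- derivs$sign[cr$idx]
      derivs$grad <- derivs$grad[cr$idx, , , drop = FALSE]
      derivs$lap <- derivs$lap[cr$idx, , drop = FALSE]
      E_L <- E_L[cr$idx]
      w <- rep(cr$weight, nw)
    }
    Eblk <- bsum / bw
    if (blk > settings$n_equil_blocks) {
      kept <- kept + 1
      blocks[kept] <- Eblk
      pops[kept] <- sum(w)
      E_est <- mean(blocks[seq_len(kept)])
    } else {
      E_est <- 0.5 * (E_est + Eblk)
    }
  }
  blk <- blocking_stderr(blocks)
  est <- energy_estimate(mean = mean(blocks), stderr = blk$stderr,
                         variance = s2 / sw - (s1 / sw)^2,
                         n_eff = blk$n_eff,
                         n_samples = settings$n_blocks)
  est$acceptance <- acc_sum / max(acc_n, 1)
  est$dtau <- settings$dtau
  est$cap_fraction <- n_cap / max(n_elocal, 1)
  if (keep_series) {
    est$block_energies <- blocks
    est$population <- pops
  }
  est
}

#' Time-step series driver for DMC extrapolation
#'
#' Runs [run_dmc()] at each time step in `taus` (same seed policy) and
#' returns a table suitable for linear tau -> 0 extrapolation.
#'
#' @inheritParams run_dmc
#' @param taus vector of time steps (a.u.)
#' @return data.frame with columns `tau`, `energy`, `stderr`; attribute
#'   `extrapolation` holds the weighted linear fit (intercept = tau -> 0
#'   energy with its standard error)
#' @export
run_dmc_tau_series <- function(params, system, settings, taus) {
  rows <- lapply(seq_along(taus), function(i) {
    s <- settings
    s$dtau <- taus[i]
    s$seed <- settings$seed + i
    r <- run_dmc(params, system, s)
    data.frame(tau = taus[i], energy = r$mean, stderr = r$stderr)
  })
  out <- do.call(rbind, rows)
  if (nrow(out) >= 2 && all(out$stderr > 0)) {
    fit <- stats::lm(energy ~ tau, data = out, weights = 1 / out$stderr^2)
    sm <- summary(fit)
    attr(out, "extrapolation") <- list(
      energy = unname(stats::coef(fit)[1]),
      stderr = sm$coefficients[1, 2],
      slope = unname(stats::coef(fit)[2]))
  }
  out
}
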