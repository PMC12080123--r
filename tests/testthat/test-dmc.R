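# Diffusion Monte Carlo: drift rescaling, capping, weights, projection

test_that("Umrigar drift rescaling has the right limits", {
  expect_equal(rescaled_drift(c(0, 0, 0), 0.005), c(0, 0, 0))
  v <- c(1e6, 0, 0)
  expect_equal(sqrt(sum(rescaled_drift(v, 0.005)^2)), sqrt(2 / 0.005),
               tolerance = 1e-3)
  v2 <- c(1e-3, 2e-3, -1e-3)            # |v|^2 tau ~ 3e-8
  expect_equal(rescaled_drift(v2, 0.005), v2, tolerance = 1e-7)
  # matrix form, monotone magnitude
  V <- rbind(c(0.1, 0, 0), c(10, 0, 0), c(1000, 0, 0))
  out <- rescaled_drift(V, 0.01)
  expect_true(all(diff(sqrt(rowSums(out^2))) > 0))
  expect_true(all(sqrt(rowSums(out^2)) <= sqrt(2 / 0.01) + 1e-12))
})

test_that("the local-energy cap clips only beyond its bound", {
  st <- dmc_settings(dtau = 0.005, alpha_cut = 0.2)
  half <- 0.2 * sqrt(5 / 0.005)
  expect_equal(half, 0.2 * sqrt(1000))   # ~6.325 hartree at N = 5
  expect_equal(capped_local_energy(-1.2, -1.0, st, 5), -1.2)
  expect_equal(capped_local_energy(-1e9, -1.0, st, 5), -1.0 - half)
  expect_equal(capped_local_energy(1e9, -1.0, st, 5), -1.0 + half)
})

test_that("the population comb preserves total weight", {
  set.seed(1)
  for (i in 1:20) {
    w <- rexp(80)
    cr <- drudeqmc:::comb_resample(w, 100)
    expect_equal(cr$weight * 100, sum(w), tolerance = 1e-12)
    expect_true(all(cr$idx >= 1 & cr$idx <= 80))
  }
})

test_that("DMC with an exact ansatz has zero variance and no bias", {
  p <- qdo_params("Ar")
  sys <- ar_qdo_system()
  r <- run_dmc(ar_exact_params(sys), sys,
               dmc_settings(target_population = 50, n_blocks = 10,
                            steps_per_block = 30, n_equil_blocks = 3,
                            seed = 2))
  expect_equal(r$mean, 1.5 * p$omega, tolerance = 1e-9)
  expect_lt(r$stderr, 1e-6)
})

test_that("DMC projects out ansatz error for nodeless systems", {
  p <- qdo_params("Ar")
  sys <- ar_qdo_system()
  parW <- ar_wrong_params(sys, factor = 1.3)
  st <- dmc_settings(target_population = 200, n_blocks = 25,
                     steps_per_block = 80, n_equil_blocks = 10, seed = 3)
  r <- run_dmc(parW, sys, st)
  expect_lt(abs(r$mean - 1.5 * p$omega), 3 * r$stderr + 5e-4)
  # and sits below the VMC energy of the same ansatz
  rv <- run_vmc(parW, sys, vmc_settings(n_steps = 250, n_walkers = 150,
                                        seed = 3))
  expect_lt(r$mean, rv$mean)
})

test_that("DMC solves hydrogen exactly from an approximate orbital", {
  hs <- h_atom_system()
  hp <- h_atom_params(hs, zeta = 0.8)
  r <- run_dmc(hp, hs, dmc_settings(target_population = 200, n_blocks = 25,
                                    steps_per_block = 200,
                                    n_equil_blocks = 8, seed = 4))
  # allowance for finite-time-step bias at dtau = 0.005 with a
  # cusp-mismatched orbital
  expect_lt(abs(r$mean + 0.5), 3 * r$stderr + 2e-3)
})

test_that("population collapse raises a diagnostic error", {
  sys <- ar_qdo_system()
  expect_error(dmc_settings(target_population = 5), "population")
})
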