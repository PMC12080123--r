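# Metropolis sampling, amplitude tuning, estimators

test_that("proposal amplitudes carry the inverse-sqrt-mass scaling", {
  sys <- el_qdo_system(qdos = list(qdo_spec(c(0, 0, 0), 1, 4, 1)))
  st <- vmc_settings(delta_e = 0.8, delta_d = 0.8)
  amps <- drudeqmc:::move_amplitudes(
    el_qdo_system(nuclei = list(nucleus(c(0, 0, 0), 1)), n_up = 1,
                  qdos = list(qdo_spec(c(0, 0, 0), 1, 4, 1))),
    st$delta_e, st$delta_d)
  expect_equal(amps[1] / amps[2], 2)        # m_e = 1 vs mu = 4
  # empirical stddev of the proposal displacement
  set.seed(1)
  disp <- t(vapply(1:30000, function(i) {
    propose_move(sys, 1, c(0, 0, 0), st)
  }, numeric(3)))
  expect_equal(sd(as.numeric(disp)), 0.8 / sqrt(4), tolerance = 0.02)
})

test_that("metropolis sweep preserves walker validity and counts moves", {
  rt <- rich_test_setup()
  set.seed(2)
  st <- vmc_settings(delta_e = 0.5, delta_d = 0.5)
  r <- metropolis_sweep(rt$params, rt$system, rt$walker, st)
  expect_s3_class(r$walker, "walker_configuration")
  expect_equal(unname(r$proposed), c(3, 2))
  expect_true(all(r$accepted <= r$proposed))
})

test_that("sampled distribution matches the closed-form |Psi|^2", {
  # single Ar QDO with the exact Gaussian: |d|^2 ~ Gamma(3/2, rate = mu w)
  p <- qdo_params("Ar")
  sys <- ar_qdo_system()
  par <- ar_exact_params(sys)
  set.seed(3)
  smp <- drudeqmc:::sample_psi2(par, sys, n_walkers = 100, n_collect = 120,
                                n_decorr = 6)
  d2 <- rowSums(smp$Xd[, 1, ]^2)
  ks <- suppressWarnings(
    ks.test(d2, function(q) pgamma(q, shape = 1.5,
                                   rate = p$mu * p$omega)))
  expect_gt(ks$p.value, 0.01)
})

test_that("amplitude tuning reaches 50 +/- 2 percent acceptance", {
  sys <- ar_qdo_system()
  par <- ar_exact_params(sys)
  set.seed(4)
  tn <- tune_amplitudes(par, sys, vmc_settings(n_walkers = 80))
  expect_true(tn$converged)
  expect_lt(abs(tn$acceptance["d"] - 0.5), 0.02)
  # absurdly large initial amplitude is tuned strictly downward
  set.seed(5)
  tn2 <- tune_amplitudes(par, sys, vmc_settings(delta_d = 60,
                                                n_walkers = 80))
  expect_lt(tn2$delta_d, 60)
  # hydrogen
  hs <- h_atom_system(); hp <- h_atom_params(hs)
  set.seed(6)
  tnh <- tune_amplitudes(hp, hs, vmc_settings(n_walkers = 80))
  expect_lt(abs(tnh$acceptance["e"] - 0.5), 0.02)
})

test_that("VMC is exact with zero variance on exact eigenstates", {
  p <- qdo_params("Ar")
  sys <- ar_qdo_system()
  r <- run_vmc(ar_exact_params(sys),
               sys, vmc_settings(n_steps = 100, n_walkers = 50, seed = 7))
  expect_equal(r$mean, 1.5 * p$omega, tolerance = 1e-10)
  expect_lt(r$variance, 1e-18)
  hs <- h_atom_system()
  rh <- run_vmc(h_atom_params(hs), hs,
                vmc_settings(n_steps = 100, n_walkers = 50, seed = 7))
  expect_equal(rh$mean, -0.5, tolerance = 1e-10)
  expect_lt(rh$variance, 1e-18)
})

test_that("VMC is variational and seed-reproducible", {
  p <- qdo_params("Ar")
  sys <- ar_qdo_system()
  parW <- ar_wrong_params(sys)
  st <- vmc_settings(n_steps = 250, n_walkers = 100, seed = 8)
  r <- run_vmc(parW, sys, st)
  # <E> for A = 2 mu w I is (3w/2)(2 + 1/2)/2 = 1.25 * 1.5w, well above
  expect_gt(r$mean, 1.5 * p$omega + 3 * r$stderr)
  r2 <- run_vmc(parW, sys, st)
  expect_identical(r$mean, r2$mean)      # bit-reproducible given the seed
})

test_that("reported error bars are calibrated against independent seeds", {
  sys <- ar_qdo_system()
  parW <- ar_wrong_params(sys)
  runs <- lapply(1:50, function(s) {
    run_vmc(parW, sys, vmc_settings(n_steps = 240, n_walkers = 20,
                                    n_equil = 60, seed = 1000 + s))
  })
  means <- vapply(runs, `[[`, 0, "mean")
  stderrs <- vapply(runs, `[[`, 0, "stderr")
  ratio <- sd(means) / mean(stderrs)
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.4)
})
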