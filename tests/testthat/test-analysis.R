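# Interaction/solvation energies, binding-energy change, PES scans

mk_est <- function(mean, stderr, config = NULL) {
  e <- energy_estimate(mean, stderr, variance = stderr^2, n_eff = 100,
                       n_samples = 100)
  if (!is.null(config)) e$config <- config
  e
}

test_that("interaction energy: additivity and quadrature propagation", {
  z <- interaction_energy(mk_est(3, 1e-3), mk_est(1, 1e-3),
                          mk_est(2, 1e-3))
  expect_equal(z$mean, 0)
  one_mev <- mev_to_hartree(1)
  z2 <- interaction_energy(mk_est(0, one_mev), mk_est(0, one_mev),
                           mk_est(0, one_mev))
  expect_equal(hartree_to_mev(z2$stderr), sqrt(3), tolerance = 1e-10)
})

test_that("mismatched run configurations are refused with a diff", {
  a <- mk_est(1, 1e-3, config = list(damping = "erf", sigma = 0.5))
  b <- mk_est(2, 1e-3, config = list(damping = "erf", sigma = 0.3))
  expect_error(interaction_energy(a, a, b), "sigma")
})

test_that("binding-energy change arithmetic and dR consistency", {
  mev <- mev_to_hartree
  d <- binding_energy_change(mk_est(mev(-10), 1e-6),
                             mk_est(mev(-6), 1e-6),
                             mk_est(mev(-5), 1e-6))
  expect_equal(hartree_to_mev(d$mean), 1, tolerance = 1e-9)
  a <- mk_est(1, 1e-3, config = list(dR = 0.5))
  b <- mk_est(1, 1e-3, config = list(dR = 1.0))
  expect_error(binding_energy_change(a, a, b), "dR")
})

test_that("unit conversions round-trip", {
  x <- c(1e-6, 0.037, 1.5)
  expect_equal(mev_to_hartree(hartree_to_mev(x)), x, tolerance = 1e-12)
  expect_equal(angstrom_to_bohr(bohr_to_angstrom(x)), x, tolerance = 1e-12)
  expect_equal(hartree_to_mev(1), 27211.386245988)
})

test_that("a one-point scan yields one row; failures are recorded", {
  sys_fn <- function(R) ar_qdo_system(center = c(0, 0, 0))
  par_fn <- function(sys) ar_exact_params(sys)
  st <- vmc_settings(n_steps = 30, n_walkers = 20, n_equil = 5)
  s1 <- pes_scan(5, sys_fn, par_fn, method = "vmc", settings = st)
  expect_equal(nrow(s1), 1)
  expect_false(s1$failed)
  # a failing point does not abort the scan
  sys_bad <- function(R) {
    if (R < 1) stop("boom") else ar_qdo_system()
  }
  expect_warning(
    s2 <- pes_scan(c(0.5, 5), sys_bad, par_fn, method = "vmc",
                   settings = st),
    "failed")
  expect_equal(nrow(s2), 2)
  expect_true(s2$failed[1] && s2$unstable[1])
  expect_false(s2$failed[2])
})

test_that("scans export CSV and JSON", {
  sys_fn <- function(R) ar_qdo_system()
  st <- vmc_settings(n_steps = 30, n_walkers = 20, n_equil = 5)
  s <- pes_scan(c(4, 5), sys_fn, function(sys) ar_exact_params(sys),
                method = "vmc", settings = st)
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_pes(s, csv = fc, json = fj)
  back <- read.csv(fc)
  expect_equal(back$energy, s$energy, tolerance = 1e-9)
  j <- jsonlite::fromJSON(fj)
  expect_equal(j$method, "vmc")
  expect_equal(nrow(j$points), 2)
})

test_that("a far-away environment contributes no solvation energy", {
  p <- qdo_params("Ar")
  hs <- h_atom_system()
  joint <- el_qdo_system(
    nuclei = list(nucleus(c(0, 0, 0), 1)), n_up = 1,
    qdos = list(qdo_spec(c(0, 0, 100), p$q, p$mu, p$omega)),
    damping = "erf", sigma = 0.5)
  env <- ar_qdo_system(center = c(0, 0, 100), damping = "erf", sigma = 0.5)
  stv <- vmc_settings(n_steps = 150, n_walkers = 60, seed = 9)
  E_joint <- run_vmc(ansatz_parameters(joint, mo = hydrogen_1s()),
                     joint, stv)
  E_sub <- run_vmc(h_atom_params(hs), hs, stv)
  E_env <- run_vmc(ansatz_parameters(env), env, stv)
  s <- solvation_energy(E_joint, E_sub, E_env)
  expect_lt(abs(s$mean), 3 * s$stderr + 1e-6)
})

test_that("duplicating a distant fragment is size-consistent", {
  # interaction energy of two QDOs at 40 bohr is unchanged (within noise)
  # when a third far-away QDO is present in both dimer and monomer runs
  p <- qdo_params("Ar")
  mk2 <- function(extra) {
    qd <- list(qdo_spec(c(0, 0, 0), p$q, p$mu, p$omega),
               qdo_spec(c(40, 0, 0), p$q, p$mu, p$omega))
    if (extra) qd <- c(qd, list(qdo_spec(c(0, 3000, 0), p$q, p$mu, p$omega)))
    el_qdo_system(qdos = qd, qdo_coupling = "dipole", damping = "none",
                  sigma = 0)
  }
  e_plain <- coupled_dipole_energy(mk2(FALSE)$qdos)$interaction
  sys3 <- mk2(TRUE)
  e_dup <- coupled_dipole_energy(sys3$qdos)$energy -
    coupled_dipole_energy(list(sys3$qdos[[1]], sys3$qdos[[3]]))$energy -
    isolated_qdo_energy(sys3$qdos[[2]])
  expect_equal(e_dup, e_plain, tolerance = 1e-6)
})

test_that("scan plotting produces a ggplot with instability highlighting", {
  skip_if_not_installed("ggplot2")
  s <- structure(
    data.frame(x = c(1, 2, 3), energy = c(0.1, 0.2, 0.15),
               stderr = rep(0.01, 3), variance = c(1, 1, 50),
               failed = rep(FALSE, 3), unstable = c(FALSE, FALSE, TRUE),
               energy_mev = c(100, 200, 150), stderr_mev = rep(10, 3)),
    class = c("pes_scan", "data.frame"))
  expect_s3_class(plot(s), "ggplot")
})
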