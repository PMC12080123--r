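# System construction, potential energy, exclusion rules, water model

test_that("isolated QDO potential reduces to the harmonic well", {
  p <- qdo_params("Ar")
  sys <- ar_qdo_system()
  w0 <- walker_configuration(drudons = rbind(c(0, 0, 0)))
  expect_equal(potential_energy(sys, w0), 0)
  w1 <- walker_configuration(drudons = rbind(c(0, 0, 1)))
  expect_equal(potential_energy(sys, w1), 0.5 * p$mu * p$omega^2,
               tolerance = 1e-12)
})

test_that("bare point-charge pair gives the Coulomb energy", {
  sys <- el_qdo_system(
    qdos = list(qdo_spec(c(50, 0, 0), 1, 1, 1, sigma = 0)),
    point_charges = list(point_charge(c(0, 0, 0), 1, sigma = 0),
                         point_charge(c(2, 0, 0), 1, sigma = 0)),
    damping = "none", sigma = 0)
  w <- walker_configuration(drudons = rbind(c(50, 0, 0)))
  terms <- potential_energy_terms(sys, w)
  pcpc <- terms[terms$type_i == "pc" & terms$type_j == "pc", ]
  expect_equal(pcpc$energy, 0.5)
})

test_that("drudon never interacts with its parental point charges", {
  O <- c(0, 0, 0); H1 <- c(1.4, 1.2, 0); H2 <- c(-1.4, 1.2, 0)
  b <- build_water_qdo(O, H1, H2)
  sys <- el_qdo_system(qdos = list(b$qdo), point_charges = b$point_charges,
                       damping = "erf", sigma = 0.5)
  for (dpos in list(c(0.3, 0.2, 0.1), c(1.3, 1.1, 0.05))) {
    terms <- potential_energy_terms(
      sys, walker_configuration(drudons = rbind(dpos)))
    expect_false(any(terms$type_i == "d" & terms$type_j == "pc"))
    expect_false(any(terms$type_i == "pc" & terms$type_j == "d"))
  }
})

test_that("exclusion bookkeeping matches the expected pair count", {
  # 2 QDOs + 3 point charges (2 parented by QDO 1, 1 by QDO 2), no electrons
  sys <- el_qdo_system(
    qdos = list(qdo_spec(c(0, 0, 0), 1, 1, 1),
                qdo_spec(c(5, 0, 0), 1, 1, 1)),
    point_charges = list(point_charge(c(0, 1, 0), 0.2, parent = 1L),
                         point_charge(c(0, -1, 0), 0.2, parent = 1L),
                         point_charge(c(5, 1, 0), -0.4, parent = 2L)),
    damping = "erf", sigma = 0.5)
  w <- walker_configuration(drudons = rbind(c(0.1, 0, 0), c(5.1, 0, 0)))
  terms <- potential_energy_terms(sys, w)
  pair_terms <- terms[terms$type_i != "well", ]
  # 7 particles (2 d, 2 c, 3 pc) -> 21 pairs, minus: 2 drudon-own-center,
  # 3 drudon-parental-pc, 3 center-own-pc
  expect_equal(nrow(pair_terms), 21 - 2 - 3 - 3)
  # and the pairwise sum plus wells equals the vectorized evaluator
  expect_equal(sum(terms$energy), potential_energy(sys, w),
               tolerance = 1e-12)
})

test_that("per-term breakdown matches the batched evaluator on a rich system", {
  rt <- rich_test_setup()
  terms <- potential_energy_terms(rt$system, rt$walker)
  expect_equal(sum(terms$energy), potential_energy(rt$system, rt$walker),
               tolerance = 1e-10)
})

test_that("potential energy is translation invariant", {
  rt <- rich_test_setup()
  v0 <- potential_energy(rt$system, rt$walker)
  shift <- c(1.7, -2.3, 0.9)
  sys2 <- el_qdo_system(
    nuclei = lapply(rt$system$nuclei,
                    function(n) nucleus(n$position + shift, n$Z)),
    n_up = rt$system$n_up, n_down = rt$system$n_down,
    qdos = lapply(rt$system$qdos, function(q) {
      q$center <- q$center + shift; q
    }),
    point_charges = lapply(rt$system$point_charges, function(p) {
      p$position <- p$position + shift; p
    }),
    damping = rt$system$damping, sigma = rt$system$sigma)
  w2 <- walker_configuration(
    electrons = sweep(rt$walker$electrons, 2, -shift),
    drudons = sweep(rt$walker$drudons, 2, -shift))
  expect_equal(potential_energy(sys2, w2), v0, tolerance = 1e-10)
})

test_that("coincident undamped charges signal divergence, not a crash", {
  sys <- el_qdo_system(
    qdos = list(qdo_spec(c(0, 0, 0), 1, 1, 1, sigma = 0)),
    point_charges = list(point_charge(c(1, 0, 0), 1, sigma = 0)),
    damping = "none", sigma = 0)
  w <- walker_configuration(drudons = rbind(c(1, 0, 0)))  # on the charge
  expect_equal(potential_energy(sys, w), -Inf)
})

test_that("damping bounds the electron-environment energy below", {
  # electron placed exactly on the QDO center: finite with sigma > 0,
  # divergent with sigma = 0 (the overpolarization mechanism)
  for (R in c(1, 2)) {
    damped <- electron_qdo_toy(R, "erf", 0.5)
    bare <- electron_qdo_toy(R, "none")
    w <- walker_configuration(electrons = rbind(c(0, 0, R)),
                              drudons = rbind(c(0.2, 0, R)))
    expect_true(is.finite(potential_energy(damped, w)))
    expect_equal(potential_energy(bare, w), -Inf)
  }
})

test_that("TIP4P water construction is neutral with M on the bisector", {
  O <- c(0, 0, 0)
  h <- 104.52 / 2 * pi / 180
  roh <- angstrom_to_bohr(0.9572)
  H1 <- roh * c(sin(h), 0, cos(h)); H2 <- roh * c(-sin(h), 0, cos(h))
  b <- build_water_qdo(O, H1, H2)
  qtot <- b$qdo$q - b$qdo$q +
    sum(vapply(b$point_charges, `[[`, 0, "charge"))
  expect_equal(qtot, 0)
  expect_equal(vapply(b$point_charges, `[[`, 0, "charge"),
               c(0.605, 0.605, -1.21))
  M <- b$point_charges[[3]]$position
  expect_equal(M[1], 0, tolerance = 1e-12)
  expect_equal(M[2], 0, tolerance = 1e-12)
  expect_equal(M[3], 0.50399, tolerance = 1e-4)   # 0.2667 Angstrom in bohr
  expect_equal(sqrt(sum((M - O)^2)), angstrom_to_bohr(0.2667),
               tolerance = 1e-12)
})

test_that("the O-M distance is invariant under rigid rotation", {
  O <- c(0.3, -1, 2)
  h <- 104.52 / 2 * pi / 180
  roh <- angstrom_to_bohr(0.9572)
  H1 <- O + roh * c(sin(h), 0, cos(h)); H2 <- O + roh * c(-sin(h), 0, cos(h))
  th <- 0.77
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- function(x) drop(Rz %*% x)
  b1 <- build_water_qdo(O, H1, H2)
  b2 <- build_water_qdo(rot(O), rot(H1), rot(H2))
  d1 <- sqrt(sum((b1$point_charges[[3]]$position - O)^2))
  d2 <- sqrt(sum((b2$point_charges[[3]]$position - rot(O))^2))
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_error(build_water_qdo(O, H1, O + (H1 - O) * 1.01), "collinear")
})

test_that("invalid domain values are rejected at construction", {
  expect_error(qdo_spec(c(0, 0, 0), q = -1, mu = 1, omega = 1), "positive")
  expect_error(nucleus(c(0, 0, 0), 0), "positive")
  expect_error(el_qdo_system(), "quantum particle")
  expect_error(el_qdo_system(
    qdos = list(qdo_spec(c(0, 0, 0), 1, 1, 1)),
    point_charges = list(point_charge(c(1, 0, 0), 1, parent = 7L))),
    "parent")
})
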