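#' Quantum Drude oscillator specification
#'
#' One QDO: a fixed center of charge +q plus a distinguishable quantum
#' particle ("drudon") of charge -q and mass mu, bound to the center by a
#' harmonic well of frequency omega. The drudon interacts with everything
#' else by (damped) Coulomb, with its own center by the quadratic well only.
#'
#' @param center 3-vector, bohr
#' @param q charge magnitude, a.u., > 0
#' @param mu drudon mass, a.u., > 0
#' @param omega oscillator frequency, a.u., > 0
#' @param sigma damping length, bohr, >= 0; `NA` means "use the system
#'   default"; 0 means bare Coulomb for every pair involving this QDO
#' @return object of class `qdo_spec`
#' @export
qdo_spec <- function(center, q, mu, omega, sigma = NA_real_) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3, is.finite(center))
  if (q <= 0 || mu <= 0 || omega <= 0) {
    stop("qdo_spec: q, mu, omega must be strictly positive")
  }
  if (!is.na(sigma) && sigma < 0) stop("qdo_spec: sigma must be >= 0")
  structure(list(center = center, q = q, mu = mu, omega = omega,
                 sigma = sigma),
            class = "qdo_spec")
}

#' Fixed point charge of the environment
#'
#' Point charges carry the static multipoles of environment molecules (e.g.
#' the TIP4P charges of a water). A point charge may belong to a parental
#' QDO, in which case that QDO's drudon does not interact with it.
#'
#' @param position 3-vector, bohr
#' @param charge signed charge, a.u.
#' @param parent index of the parental QDO in the system's QDO list, or
#'   `NA` for a free point charge
#' @param sigma damping length, bohr (>= 0) or `NA` for the system default
#' @return object of class `point_charge`
#' @export
point_charge <- function(position, charge, parent = NA_integer_,
                         sigma = NA_real_) {
  position <- as.numeric(position)
  stopifnot(length(position) == 3, is.finite(position), is.finite(charge))
  if (!is.na(sigma) && sigma < 0) stop("point_charge: sigma must be >= 0")
  structure(list(position = position, charge = charge,
                 parent = as.integer(parent), sigma = sigma),
            class = "point_charge")
}

#' Nucleus of the explicit electronic subsystem
#'
#' @param position 3-vector, bohr
#' @param Z positive integer nuclear charge
#' @return object of class `nucleus`
#' @export
nucleus <- function(position, Z) {
  position <- as.numeric(position)
  stopifnot(length(position) == 3, is.finite(position))
  if (Z < 1 || Z != round(Z)) stop("nucleus: Z must be a positive integer")
  structure(list(position = position, Z = as.numeric(Z)), class = "nucleus")
}

#' Built-in QDO parameters (atomic units)
#'
#' Leading-order response parametrization of argon and water: charge q,
#' frequency omega and drudon mass mu reproducing the species'
#' dipole polarizability alpha = q^2/(mu omega^2) and leading dispersion
#' coefficients.
#'
#' @param species `"Ar"` or `"H2O"`
#' @return list with elements `q`, `omega`, `mu`
#' @export
#' @examples
#' qdo_params("Ar")
qdo_params <- function(species) {
  switch(match.arg(species, c("Ar", "H2O")),
    Ar  = list(q = 1.3314, omega = 0.7272, mu = 0.3020),
    H2O = list(q = 1.1973, omega = 0.6287, mu = 0.3656)
  )
}

#' Joint electron + QDO-environment system
#'
#' Defines the full Hamiltonian: an electronic subsystem (nuclei + electrons,
#' bare Coulomb internally), an environment of QDOs and point charges
#' (internally coupled by damped Coulomb), and the damped Coulomb coupling
#' between the two subsystems. Interaction exclusions: each drudon skips the
#' Coulomb term with its own center (quadratic well instead) and with its
#' parental point charges; optionally each center skips its own point
#' charges (rigid intramolecular constants).
#'
#' @param nuclei list of [nucleus()] (may be empty)
#' @param n_up,n_down electron counts per spin
#' @param qdos list of [qdo_spec()]
#' @param point_charges list of [point_charge()]
#' @param damping damping kernel, see [DAMPING_KINDS]
#' @param sigma global default damping length (bohr) applied to environment
#'   members whose own sigma is `NA`
#' @param sigma_e damping length attached to electrons and nuclei for
#'   cross-subsystem pairs (default: `sigma`)
#' @param qdo_coupling `"coulomb"` for full Coulomb between QDO pairs, or
#'   `"dipole"` for the dipole-truncated coupling
#'   q_i q_j d_i' T(R_ij) d_j between drudon displacements (used to compare
#'   against the closed-form coupled-dipole oracle)
#' @param exclude_center_own_pc exclude the (constant) interaction of a QDO
#'   center with its own point charges (default TRUE)
#' @return object of class `el_qdo_system`
#' @export
el_qdo_system <- function(nuclei = list(), n_up = 0L, n_down = 0L,
                          qdos = list(), point_charges = list(),
                          damping = "erf", sigma = 0.5, sigma_e = sigma,
                          qdo_coupling = c("coulomb", "dipole"),
                          exclude_center_own_pc = TRUE) {
  damping <- match.arg(damping, DAMPING_KINDS)
  qdo_coupling <- match.arg(qdo_coupling)
  if (sigma < 0 || sigma_e < 0) stop("el_qdo_system: sigma must be >= 0")
  n_up <- as.integer(n_up); n_down <- as.integer(n_down)
  if (n_up < 0 || n_down < 0) stop("el_qdo_system: negative electron count")
  n_e <- n_up + n_down
  if (n_e > 0 && length(nuclei) == 0) {
    stop("el_qdo_system: electrons require at least one nucleus")
  }
  if (n_e == 0 && length(qdos) == 0) {
    stop("el_qdo_system: need at least one quantum particle")
  }
  stopifnot(all(vapply(nuclei, inherits, TRUE, "nucleus")),
            all(vapply(qdos, inherits, TRUE, "qdo_spec")),
            all(vapply(point_charges, inherits, TRUE, "point_charge")))
  n_q <- length(qdos)
  for (pc in point_charges) {
    if (!is.na(pc$parent) && (pc$parent < 1 || pc$parent > n_q)) {
      stop("el_qdo_system: point-charge parent index out of range")
    }
  }
  fill <- function(s) ifelse(is.na(s), sigma, s)
  sys <- structure(list(
    nuclei = nuclei, n_up = n_up, n_down = n_down,
    qdos = qdos, point_charges = point_charges,
    damping = damping, sigma = sigma, sigma_e = sigma_e,
    qdo_coupling = qdo_coupling,
    exclude_center_own_pc = exclude_center_own_pc,
    # dense views for vectorized evaluation
    Rn = do.call(rbind, c(lapply(nuclei, `[[`, "position"), list(matrix(0, 0, 3)))),
    Zn = vapply(nuclei, `[[`, 0, "Z"),
    Rc = do.call(rbind, c(lapply(qdos, `[[`, "center"), list(matrix(0, 0, 3)))),
    qq = vapply(qdos, `[[`, 0, "q"),
    mu = vapply(qdos, `[[`, 0, "mu"),
    omega = vapply(qdos, `[[`, 0, "omega"),
    sigma_q = fill(vapply(qdos, function(x) x$sigma, 0)),
    Rpc = do.call(rbind, c(lapply(point_charges, `[[`, "position"), list(matrix(0, 0, 3)))),
    Qpc = vapply(point_charges, `[[`, 0, "charge"),
    parent = vapply(point_charges, `[[`, 0L, "parent"),
    sigma_pc = fill(vapply(point_charges, function(x) x$sigma, 0))
  ), class = "el_qdo_system")
  sys
}

#' @export
print.el_qdo_system <- function(x, ...) {
  cat("<el_qdo_system>\n")
  cat(sprintf("  electrons: %d up + %d down, nuclei: %d\n",
              x$n_up, x$n_down, length(x$nuclei)))
  cat(sprintf("  QDOs: %d, point charges: %d\n",
              length(x$qdos), length(x$point_charges)))
  cat(sprintf("  damping: %s (sigma = %g bohr), QDO coupling: %s\n",
              x$damping, x$sigma, x$qdo_coupling))
  invisible(x)
}

n_electrons <- function(system) system$n_up + system$n_down
n_qdos <- function(system) length(system$qdos)
n_quantum_particles <- function(system) n_electrons(system) + n_qdos(system)

#' Masses of the quantum particles (electrons first, then drudons)
#' @param system an [el_qdo_system()]
#' @return numeric vector of length N_e + N_Q
#' @export
particle_masses <- function(system) {
  c(rep(1, n_electrons(system)), system$mu)
}

#' Walker configuration
#'
#' Joint coordinates of all quantum particles: electrons (spin-up block
#' first) and drudons, plus a nonnegative weight.
#'
#' @param electrons N_e x 3 matrix, bohr (may have 0 rows)
#' @param drudons N_Q x 3 matrix, bohr (may have 0 rows)
#' @param weight nonnegative scalar
#' @return object of class `walker_configuration`
#' @export
walker_configuration <- function(electrons = matrix(0, 0, 3),
                                 drudons = matrix(0, 0, 3), weight = 1) {
  electrons <- rbind(matrix(0, 0, 3), as.matrix(electrons))
  drudons <- rbind(matrix(0, 0, 3), as.matrix(drudons))
  stopifnot(ncol(electrons) == 3, ncol(drudons) == 3, weight >= 0)
  structure(list(electrons = electrons, drudons = drudons, weight = weight),
            class = "walker_configuration")
}

check_walker <- function(system, walker) {
  stopifnot(inherits(walker, "walker_configuration"))
  if (nrow(walker$electrons) != n_electrons(system) ||
      nrow(walker$drudons) != n_qdos(system)) {
    stop("walker does not match system particle counts")
  }
  invisible(TRUE)
}

# TIP4P charge constants (a.u. of charge) and O-M distance (Angstrom)
TIP4P_QH <- 0.605
TIP4P_QM <- -1.21
TIP4P_ROM_ANGSTROM <- 0.2667

#' Build a water QDO with TIP4P point charges from atomistic positions
#'
#' Constructs the four-site water model: +0.605 on each hydrogen, -1.21 on
#' the M site placed on the HOH bisector at 0.2667 Angstrom from the oxygen
#' (on the hydrogen side), and a water-parametrized QDO. Oxygen carries no
#' charge; it only defines the geometry. The oscillator is attached at the M
#' site by default (the model's center of charge); `center_site = "O"` is
#' available since the attachment point is a modelling choice.
#'
#' @param O,H1,H2 3-vectors, bohr
#' @param center_site `"M"` (default) or `"O"`
#' @param sigma damping length for the QDO and its point charges (`NA` =
#'   system default)
#' @return list with elements `qdo` ([qdo_spec()]) and `point_charges`
#'   (list of 3 [point_charge()]; parent indices must be relabelled by the
#'   caller to the QDO's position in the final system, see
#'   [waters_to_environment()])
#' @export
build_water_qdo <- function(O, H1, H2, center_site = c("M", "O"),
                            sigma = NA_real_) {
  center_site <- match.arg(center_site)
  O <- as.numeric(O); H1 <- as.numeric(H1); H2 <- as.numeric(H2)
  u1 <- H1 - O; u2 <- H2 - O
  n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
  if (n1 < 1e-8 || n2 < 1e-8) stop("build_water_qdo: degenerate O-H bond")
  cr <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  if (sqrt(sum(cr^2)) / (n1 * n2) < 1e-6) {
    stop("build_water_qdo: collinear water geometry")
  }
  bis <- u1 / n1 + u2 / n2
  nb <- sqrt(sum(bis^2))
  if (nb < 1e-8) stop("build_water_qdo: collinear water geometry")
  M <- O + angstrom_to_bohr(TIP4P_ROM_ANGSTROM) * bis / nb
  p <- qdo_params("H2O")
  ctr <- if (center_site == "M") M else O
  list(
    qdo = qdo_spec(ctr, q = p$q, mu = p$mu, omega = p$omega, sigma = sigma),
    point_charges = list(
      point_charge(H1, TIP4P_QH, parent = 1L, sigma = sigma),
      point_charge(H2, TIP4P_QH, parent = 1L, sigma = sigma),
      point_charge(M, TIP4P_QM, parent = 1L, sigma = sigma)
    )
  )
}

#' Assemble a QDO + point-charge environment from water geometries
#'
#' @param waters list of waters, each a list with 3-vectors `O`, `H1`, `H2`
#'   (bohr)
#' @inheritParams build_water_qdo
#' @return list with `qdos` and `point_charges` ready for
#'   [el_qdo_system()], parent indices wired to each water's QDO
#' @export
waters_to_environment <- function(waters, center_site = "M",
                                  sigma = NA_real_) {
  qdos <- list(); pcs <- list()
  for (i in seq_along(waters)) {
    w <- waters[[i]]
    b <- build_water_qdo(w$O, w$H1, w$H2, center_site = center_site,
                         sigma = sigma)
    qdos[[i]] <- b$qdo
    for (pc in b$point_charges) {
      pc$parent <- i
      pcs[[length(pcs) + 1L]] <- pc
    }
  }
  list(qdos = qdos, point_charges = pcs)
}
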