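#' @title Potential energy of the joint electron + QDO system
#' @description
#' The total potential is the sum of (a) the harmonic wells binding each
#' drudon to its center, (b) the bare-Coulomb electronic subsystem
#' (electron-electron, electron-nucleus, nucleus-nucleus), (c) all
#' environment-internal Coulomb pairs and (d) all cross
#' electronic-environment pairs, the latter two damped by the system's
#' kernel. Exclusions: drudon vs its own center (the well replaces it),
#' drudon vs its parental point charges, and (by default) a center vs its
#' own point charges.
#' @name potential
NULL

dist_pp <- function(A, B) sqrt(rowSums((A - B)^2))

# distances between one moving particle (nw x 3) and fixed sites (nf x 3):
# returns nw x nf
dist_pf <- function(A, F) {
  dx <- outer(A[, 1], F[, 1], "-")
  dy <- outer(A[, 2], F[, 2], "-")
  dz <- outer(A[, 3], F[, 3], "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}

# constant energy of all fixed-fixed pairs (nuclei, centers, point charges)
fixed_pair_energy <- function(system) {
  kind <- system$damping
  e <- 0
  Zn <- system$Zn; Rn <- system$Rn
  qq <- system$qq; Rc <- system$Rc; sq <- system$sigma_q
  Qpc <- system$Qpc; Rpc <- system$Rpc; spc <- system$sigma_pc
  nn <- length(Zn); nq <- length(qq); npc <- length(Qpc)
  dip <- system$qdo_coupling == "dipole"
  # nucleus-nucleus, bare
  if (nn > 1) {
    for (i in 1:(nn - 1)) for (j in (i + 1):nn) {
      e <- e + Zn[i] * Zn[j] / sqrt(sum((Rn[i, ] - Rn[j, ])^2))
    }
  }
  # center-center, damped (absent in dipole-truncated QDO coupling)
  if (nq > 1 && !dip) {
    for (i in 1:(nq - 1)) for (j in (i + 1):nq) {
      r <- sqrt(sum((Rc[i, ] - Rc[j, ])^2))
      e <- e + qq[i] * qq[j] * damped_coulomb(kind, r, pair_sigma(sq[i], sq[j]))
    }
  }
  # nucleus-center, damped
  if (nn > 0 && nq > 0) {
    for (i in seq_len(nn)) for (j in seq_len(nq)) {
      r <- sqrt(sum((Rn[i, ] - Rc[j, ])^2))
      e <- e + Zn[i] * qq[j] * damped_coulomb(kind, r, pair_sigma(system$sigma_e, sq[j]))
    }
  }
  # nucleus-pc, damped
  if (nn > 0 && npc > 0) {
    for (i in seq_len(nn)) for (j in seq_len(npc)) {
      r <- sqrt(sum((Rn[i, ] - Rpc[j, ])^2))
      e <- e + Zn[i] * Qpc[j] * damped_coulomb(kind, r, pair_sigma(system$sigma_e, spc[j]))
    }
  }
  # center-pc, damped, optionally excluding own
  if (nq > 0 && npc > 0) {
    for (i in seq_len(nq)) for (j in seq_len(npc)) {
      if (system$exclude_center_own_pc && !is.na(system$parent[j]) &&
          system$parent[j] == i) next
      r <- sqrt(sum((Rc[i, ] - Rpc[j, ])^2))
      e <- e + qq[i] * Qpc[j] * damped_coulomb(kind, r, pair_sigma(sq[i], spc[j]))
    }
  }
  # pc-pc, damped
  if (npc > 1) {
    for (i in 1:(npc - 1)) for (j in (i + 1):npc) {
      r <- sqrt(sum((Rpc[i, ] - Rpc[j, ])^2))
      e <- e + Qpc[i] * Qpc[j] * damped_coulomb(kind, r, pair_sigma(spc[i], spc[j]))
    }
  }
  e
}

# Batched potential over a walker population.
# Xe: nw x N_e x 3 array (or NULL), Xd: nw x N_Q x 3 array (or NULL).
potential_energy_batch <- function(system, Xe, Xd) {
  ne <- n_electrons(system); nq <- n_qdos(system)
  nw <- if (ne > 0) dim(Xe)[1] else dim(Xd)[1]
  kind <- system$damping
  se <- system$sigma_e; sq <- system$sigma_q; spc <- system$sigma_pc
  V <- rep(fixed_pair_energy(system), nw)
  dip <- system$qdo_coupling == "dipole"

  # harmonic wells
  if (nq > 0) {
    for (i in seq_len(nq)) {
      d <- Xd[, i, , drop = FALSE]; dim(d) <- c(nw, 3)
      d <- sweep(d, 2, system$Rc[i, ])
      V <- V + 0.5 * system$mu[i] * system$omega[i]^2 * rowSums(d * d)
    }
  }
  # electron-electron (bare) and electron-nucleus (bare)
  if (ne > 1) {
    for (i in 1:(ne - 1)) for (j in (i + 1):ne) {
      V <- V + 1 / dist_pp(mslice(Xe, i), mslice(Xe, j))
    }
  }
  if (ne > 0 && length(system$Zn) > 0) {
    for (i in seq_len(ne)) {
      r <- dist_pf(mslice(Xe, i), system$Rn)
      V <- V - drop(r^-1 %*% system$Zn)
    }
  }
  # electron vs environment (damped): centers, drudons, point charges
  if (ne > 0 && nq > 0) {
    for (i in seq_len(ne)) {
      re <- mslice(Xe, i)
      rc <- dist_pf(re, system$Rc)
      for (j in seq_len(nq)) {
        V <- V - system$qq[j] *
          damped_coulomb(kind, rc[, j], pair_sigma(se, sq[j]))
        rdj <- dist_pp(re, mslice(Xd, j))
        V <- V + system$qq[j] *
          damped_coulomb(kind, rdj, pair_sigma(se, sq[j]))
      }
    }
  }
  if (ne > 0 && length(system$Qpc) > 0) {
    for (i in seq_len(ne)) {
      r <- dist_pf(mslice(Xe, i), system$Rpc)
      for (j in seq_along(system$Qpc)) {
        V <- V - system$Qpc[j] *
          damped_coulomb(kind, r[, j], pair_sigma(se, spc[j]))
      }
    }
  }
  # drudon vs nuclei (damped)
  if (nq > 0 && length(system$Zn) > 0) {
    for (i in seq_len(nq)) {
      r <- dist_pf(mslice(Xd, i), system$Rn)
      for (j in seq_along(system$Zn)) {
        V <- V - system$Zn[j] * system$qq[i] *
          damped_coulomb(kind, r[, j], pair_sigma(se, sq[i]))
      }
    }
  }
  # drudon vs point charges (damped, parental excluded)
  if (nq > 0 && length(system$Qpc) > 0) {
    for (i in seq_len(nq)) {
      r <- dist_pf(mslice(Xd, i), system$Rpc)
      for (j in seq_along(system$Qpc)) {
        if (!is.na(system$parent[j]) && system$parent[j] == i) next
        V <- V - system$Qpc[j] * system$qq[i] *
          damped_coulomb(kind, r[, j], pair_sigma(sq[i], spc[j]))
      }
    }
  }
  # QDO-QDO coupling
  if (nq > 1) {
    for (i in 1:(nq - 1)) for (j in (i + 1):nq) {
      if (dip) {
        Rij <- system$Rc[j, ] - system$Rc[i, ]
        R <- sqrt(sum(Rij^2)); nh <- Rij / R
        di <- sweep(mslice(Xd, i), 2, system$Rc[i, ])
        dj <- sweep(mslice(Xd, j), 2, system$Rc[j, ])
        V <- V + system$qq[i] * system$qq[j] / R^3 *
          (rowSums(di * dj) - 3 * drop(di %*% nh) * drop(dj %*% nh))
      } else {
        sp <- pair_sigma(sq[i], sq[j])
        rdd <- dist_pp(mslice(Xd, i), mslice(Xd, j))
        V <- V + system$qq[i] * system$qq[j] * damped_coulomb(kind, rdd, sp)
        rdc <- dist_pf(mslice(Xd, i), system$Rc[j, , drop = FALSE])[, 1]
        V <- V - system$qq[i] * system$qq[j] * damped_coulomb(kind, rdc, sp)
        rcd <- dist_pf(mslice(Xd, j), system$Rc[i, , drop = FALSE])[, 1]
        V <- V - system$qq[i] * system$qq[j] * damped_coulomb(kind, rcd, sp)
      }
    }
  }
  V
}

# nw x 3 slice of particle i from an nw x np x 3 array
mslice <- function(X, i) {
  out <- X[, i, , drop = FALSE]
  dim(out) <- c(dim(X)[1], 3)
  out
}

#' Total potential energy of one walker configuration
#'
#' @param system an [el_qdo_system()]
#' @param walker a [walker_configuration()] matching the system
#' @return potential energy, hartree; `Inf`/`-Inf` signal a Coulomb
#'   divergence (coincident undamped charges)
#' @export
#' @examples
#' p <- qdo_params("Ar")
#' sys <- el_qdo_system(qdos = list(qdo_spec(c(0, 0, 0), p$q, p$mu, p$omega)))
#' w <- walker_configuration(drudons = rbind(c(0, 0, 1)))
#' potential_energy(sys, w)  # 0.5 * mu * omega^2
potential_energy <- function(system, walker) {
  check_walker(system, walker)
  # walker matrices are (np x 3); batch layout is (nw, np, 3) with nw = 1
  Xe <- aperm(array(t(walker$electrons), c(3, nrow(walker$electrons), 1)), c(3, 2, 1))
  Xd <- aperm(array(t(walker$drudons), c(3, nrow(walker$drudons), 1)), c(3, 2, 1))
  potential_energy_batch(system,
                         if (nrow(walker$electrons)) Xe else NULL,
                         if (nrow(walker$drudons)) Xd else NULL)
}

#' Per-pair breakdown of the potential energy
#'
#' Slow diagnostic double loop over an explicit particle table, written
#' independently of the vectorized evaluator; lists every included pair term
#' (and the harmonic wells) so exclusion rules can be audited term by term.
#'
#' @inheritParams potential_energy
#' @return data.frame with columns `type_i`, `idx_i`, `type_j`, `idx_j`
#'   (types: `e` electron, `n` nucleus, `d` drudon, `c` center, `pc` point
#'   charge, `well` harmonic well), `damped`, `r` (bohr; NA for wells) and
#'   `energy` (hartree)
#' @export
potential_energy_terms <- function(system, walker) {
  check_walker(system, walker)
  tab <- list()
  add_row <- function(type, idx, pos, charge, sigma, qdo = NA, parent = NA) {
    tab[[length(tab) + 1L]] <<- list(type = type, idx = idx, pos = pos,
                                     charge = charge, sigma = sigma,
                                     qdo = qdo, parent = parent)
  }
  for (i in seq_len(n_electrons(system))) {
    add_row("e", i, walker$electrons[i, ], -1, system$sigma_e)
  }
  for (i in seq_along(system$Zn)) {
    add_row("n", i, system$Rn[i, ], system$Zn[i], system$sigma_e)
  }
  for (i in seq_len(n_qdos(system))) {
    add_row("d", i, walker$drudons[i, ], -system$qq[i], system$sigma_q[i],
            qdo = i)
    add_row("c", i, system$Rc[i, ], system$qq[i], system$sigma_q[i], qdo = i)
  }
  for (i in seq_along(system$Qpc)) {
    add_row("pc", i, system$Rpc[i, ], system$Qpc[i], system$sigma_pc[i],
            parent = system$parent[i])
  }
  electronic <- c("e", "n")
  out <- list()
  np <- length(tab)
  if (np >= 2) {
    for (a in 1:(np - 1)) for (b in (a + 1):np) {
      pi <- tab[[a]]; pj <- tab[[b]]
      # exclusion rules
      tt <- sort(c(pi$type, pj$type))
      if (identical(tt, c("c", "d")) &&
          !is.na(pi$qdo) && !is.na(pj$qdo) && pi$qdo == pj$qdo) next
      if (identical(tt, c("d", "pc"))) {
        dq <- if (pi$type == "d") pi$qdo else pj$qdo
        pp <- if (pi$type == "pc") pi$parent else pj$parent
        if (!is.na(pp) && pp == dq) next
      }
      if (identical(tt, c("c", "pc")) && system$exclude_center_own_pc) {
        cq <- if (pi$type == "c") pi$qdo else pj$qdo
        pp <- if (pi$type == "pc") pi$parent else pj$parent
        if (!is.na(pp) && pp == cq) next
      }
      if (system$qdo_coupling == "dipole" &&
          pi$type %in% c("d", "c") && pj$type %in% c("d", "c") &&
          pi$qdo != pj$qdo) next  # handled by the dipole-pair term below
      damped <- !(pi$type %in% electronic && pj$type %in% electronic)
      r <- sqrt(sum((pi$pos - pj$pos)^2))
      en <- if (damped) {
        pi$charge * pj$charge *
          damped_coulomb(system$damping, r, pair_sigma(pi$sigma, pj$sigma))
      } else {
        pi$charge * pj$charge / r
      }
      out[[length(out) + 1L]] <- data.frame(
        type_i = pi$type, idx_i = pi$idx, type_j = pj$type, idx_j = pj$idx,
        damped = damped, r = r, energy = en)
    }
  }
  for (i in seq_len(n_qdos(system))) {
    d <- walker$drudons[i, ] - system$Rc[i, ]
    out[[length(out) + 1L]] <- data.frame(
      type_i = "well", idx_i = i, type_j = "well", idx_j = i,
      damped = FALSE, r = NA_real_,
      energy = 0.5 * system$mu[i] * system$omega[i]^2 * sum(d^2))
  }
  if (system$qdo_coupling == "dipole" && n_qdos(system) > 1) {
    nq <- n_qdos(system)
    for (i in 1:(nq - 1)) for (j in (i + 1):nq) {
      Rij <- system$Rc[j, ] - system$Rc[i, ]
      R <- sqrt(sum(Rij^2)); nh <- Rij / R
      di <- walker$drudons[i, ] - system$Rc[i, ]
      dj <- walker$drudons[j, ] - system$Rc[j, ]
      out[[length(out) + 1L]] <- data.frame(
        type_i = "d", idx_i = i, type_j = "d", idx_j = j,
        damped = FALSE, r = R,
        energy = system$qq[i] * system$qq[j] / R^3 *
          (sum(di * dj) - 3 * sum(di * nh) * sum(dj * nh)))
    }
  }
  do.call(rbind, out)
}
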