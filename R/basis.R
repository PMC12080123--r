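#' Atomic basis function (contracted Cartesian GTO or 1s STO)
#'
#' Cartesian Gaussian: phi(r) = sum_k c_k (x^lx y^ly z^lz) exp(-a_k |r-R|^2)
#' with (x,y,z) = r - R. The `"sto"` type is the hydrogenic 1s exponential
#' exp(-zeta |r-R|) used for the all-electron test atoms, so no external
#' quantum-chemistry code is needed to build exact hydrogen orbitals.
#'
#' @param center 3-vector, bohr
#' @param l angular momentum triplet (lx, ly, lz); must be c(0,0,0) for STO
#' @param exponents primitive exponents (> 0)
#' @param coefficients contraction coefficients (same length)
#' @param type `"gto"` or `"sto"`
#' @return object of class `basis_function`
#' @export
basis_function <- function(center, l = c(0L, 0L, 0L), exponents,
                           coefficients = rep(1, length(exponents)),
                           type = c("gto", "sto")) {
  type <- match.arg(type)
  stopifnot(length(center) == 3, length(l) == 3,
            length(exponents) == length(coefficients), all(exponents > 0))
  if (type == "sto" && (any(l != 0) || length(exponents) != 1)) {
    stop("basis_function: sto supports a single 1s exponential only")
  }
  structure(list(center = as.numeric(center), l = as.integer(l),
                 exponents = as.numeric(exponents),
                 coefficients = as.numeric(coefficients), type = type),
            class = "basis_function")
}

# x^p with the p <= 0 conventions needed by polynomial derivatives:
# p == 0 -> 1 (also at x = 0); p < 0 -> 0 (always multiplied by factor 0)
powsafe <- function(x, p) {
  if (p < 0) return(rep(0, length(x)))
  if (p == 0) return(rep(1, length(x)))
  x^p
}

#' Evaluate a basis function with gradient and Laplacian
#'
#' @param bf a [basis_function()]
#' @param R n x 3 matrix of evaluation points (bohr)
#' @return list with `val` (n), `grad` (n x 3), `lap` (n)
#' @export
eval_basis <- function(bf, R) {
  R <- matrix(R, ncol = 3)
  n <- nrow(R)
  d <- sweep(R, 2, bf$center)
  if (bf$type == "sto") {
    r <- pmax(sqrt(rowSums(d * d)), 1e-12)
    z <- bf$exponents[1]
    v <- bf$coefficients[1] * exp(-z * r)
    return(list(val = v,
                grad = -z * v / r * d,
                lap = (z^2 - 2 * z / r) * v))
  }
  l <- bf$l
  s2 <- rowSums(d * d)
  val <- numeric(n); grad <- matrix(0, n, 3); lap <- numeric(n)
  px <- powsafe(d[, 1], l[1]); py <- powsafe(d[, 2], l[2])
  pz <- powsafe(d[, 3], l[3])
  P <- px * py * pz
  for (k in seq_along(bf$exponents)) {
    a <- bf$exponents[k]
    g <- bf$coefficients[k] * exp(-a * s2)
    val <- val + g * P
    for (c3 in 1:3) {
      lc <- l[c3]
      rest <- switch(c3, py * pz, px * pz, px * py)  # other two axes
      dpoly <- lc * powsafe(d[, c3], lc - 1) - 2 * a * powsafe(d[, c3], lc + 1)
      grad[, c3] <- grad[, c3] + g * rest * dpoly
      d2poly <- lc * (lc - 1) * powsafe(d[, c3], lc - 2) -
        2 * a * (2 * lc + 1) * powsafe(d[, c3], lc) +
        4 * a^2 * powsafe(d[, c3], lc + 2)
      lap <- lap + g * rest * d2poly
    }
  }
  list(val = val, grad = grad, lap = lap)
}

# value-only basis evaluation (no derivatives): used on hot paths
basis_value <- function(bf, R) {
  R <- matrix(R, ncol = 3)
  d <- sweep(R, 2, bf$center)
  if (bf$type == "sto") {
    r <- pmax(sqrt(rowSums(d * d)), 1e-12)
    return(bf$coefficients[1] * exp(-bf$exponents[1] * r))
  }
  s2 <- rowSums(d * d)
  P <- powsafe(d[, 1], bf$l[1]) * powsafe(d[, 2], bf$l[2]) *
    powsafe(d[, 3], bf$l[3])
  v <- 0
  for (k in seq_along(bf$exponents)) {
    v <- v + bf$coefficients[k] * exp(-bf$exponents[k] * s2)
  }
  v * P
}

#' Molecular orbital set over a basis
#'
#' @param basis list of [basis_function()]
#' @param coefficients n_basis x n_orbital matrix of MO coefficients
#' @return object of class `mo_set`
#' @export
mo_set <- function(basis, coefficients) {
  coefficients <- as.matrix(coefficients)
  stopifnot(all(vapply(basis, inherits, TRUE, "basis_function")),
            nrow(coefficients) == length(basis))
  structure(list(basis = basis, coefficients = coefficients),
            class = "mo_set")
}

#' Evaluate molecular orbitals with gradients and Laplacians
#'
#' @param mo an [mo_set()]
#' @param R n x 3 matrix of electron positions (bohr)
#' @return list with `val` (n x n_orb), `grad` (n x n_orb x 3), `lap`
#'   (n x n_orb)
#' @export
eval_mos <- function(mo, R) {
  R <- matrix(R, ncol = 3)
  n <- nrow(R); nb <- length(mo$basis); no <- ncol(mo$coefficients)
  bval <- matrix(0, n, nb); blap <- matrix(0, n, nb)
  bgrad <- array(0, c(n, nb, 3))
  for (q in seq_len(nb)) {
    e <- eval_basis(mo$basis[[q]], R)
    bval[, q] <- e$val; blap[, q] <- e$lap; bgrad[, q, ] <- e$grad
  }
  grad <- array(0, c(n, no, 3))
  for (c3 in 1:3) grad[, , c3] <- bgrad[, , c3] %*% mo$coefficients
  list(val = bval %*% mo$coefficients,
       grad = grad,
       lap = blap %*% mo$coefficients)
}

#' Exact hydrogenic 1s orbital set
#'
#' @param center nuclear position, bohr
#' @param zeta orbital exponent (1 = exact hydrogen ground state)
#' @return an [mo_set()] with one orbital
#' @export
hydrogen_1s <- function(center = c(0, 0, 0), zeta = 1) {
  mo_set(list(basis_function(center, exponents = zeta, type = "sto")),
         matrix(1, 1, 1))
}

#' Read a molecular-orbital file (JSON)
#'
#' Plain-text interchange for orbitals produced elsewhere. Schema:
#' `{"basis": [{"center": [x,y,z] (bohr) | "center_index": i,
#' "l": [lx,ly,lz], "exponents": [...], "coefficients": [...],
#' "type": "gto"|"sto"}, ...], "mo_coefficients": [[...], ...]}`
#' where `mo_coefficients` is n_basis x n_orbitals. `center_index` refers to
#' the supplied nuclei. Converting a quantum-chemistry text output amounts
#' to writing this JSON with the program's basis exponents/contractions and
#' its MO coefficient matrix.
#'
#' @param path JSON file path
#' @param nuclei optional list of [nucleus()] used to resolve
#'   `center_index`
#' @return an [mo_set()]
#' @export
read_orbitals <- function(path, nuclei = NULL) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  basis <- lapply(j$basis, function(b) {
    ctr <- if (!is.null(b$center_index)) {
      if (is.null(nuclei)) stop("read_orbitals: center_index needs nuclei")
      nuclei[[b$center_index]]$position
    } else unlist(b$center)
    basis_function(ctr,
                   l = if (is.null(b$l)) c(0L, 0L, 0L) else unlist(b$l),
                   exponents = unlist(b$exponents),
                   coefficients = if (is.null(b$coefficients)) {
                     rep(1, length(unlist(b$exponents)))
                   } else unlist(b$coefficients),
                   type = if (is.null(b$type)) "gto" else b$type)
  })
  coef <- do.call(rbind, lapply(j$mo_coefficients, unlist))
  mo_set(basis, coef)
}

#' Default uncontracted Jastrow basis for a set of nuclei
#'
#' 3s2p1d-style shells for heavy atoms and 2s1p for hydrogen (even-tempered
#' exponents), the standard recipe for the inhomogeneous Jastrow term.
#'
#' @param nuclei list of [nucleus()]
#' @param scale overall exponent scale
#' @return list of [basis_function()]
#' @export
default_jastrow_basis <- function(nuclei, scale = 1) {
  out <- list()
  shells_p <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  shells_d <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
                    c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  for (nuc in nuclei) {
    heavy <- nuc$Z > 1
    s_exps <- if (heavy) scale * c(0.25, 1, 4) else scale * c(0.3, 1.2)
    for (a in s_exps) {
      out[[length(out) + 1L]] <- basis_function(nuc$position, exponents = a)
    }
    p_exps <- if (heavy) scale * c(0.4, 1.6) else scale * 0.8
    for (a in p_exps) for (s in seq_len(nrow(shells_p))) {
      out[[length(out) + 1L]] <-
        basis_function(nuc$position, l = shells_p[s, ], exponents = a)
    }
    if (heavy) {
      for (s in seq_len(nrow(shells_d))) {
        out[[length(out) + 1L]] <-
          basis_function(nuc$position, l = shells_d[s, ], exponents = scale)
      }
    }
  }
  out
}
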