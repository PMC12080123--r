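#' Read an XYZ geometry file
#'
#' Standard XYZ: first line atom count, second a comment, then
#' `species x y z` in Angstrom.
#'
#' @param path file path
#' @return list with `species` (character), `coords` (n x 3 matrix,
#'   Angstrom), `comment`
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "\\s+")
  species <- vapply(parts, `[[`, "", 1)
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  list(species = species, coords = coords, comment = trimws(lines[2]))
}

#' Write an XYZ geometry file
#'
#' @param species character vector of element symbols
#' @param coords n x 3 matrix, Angstrom
#' @param path file path
#' @param comment comment line
#' @export
write_xyz <- function(species, coords, path, comment = "") {
  lines <- c(as.character(length(species)), comment,
             sprintf("%-3s %16.8f %16.8f %16.8f", species,
                     coords[, 1], coords[, 2], coords[, 3]))
  writeLines(lines, path)
}

#' Group an O/H/H atom list into water molecules
#'
#' Assumes waters are listed as consecutive O, H, H triplets (the common
#' cage-file convention).
#'
#' @param species character vector
#' @param coords n x 3 matrix (any length unit; preserved)
#' @return list of waters, each `list(O =, H1 =, H2 =)`
#' @export
waters_from_atoms <- function(species, coords) {
  n <- length(species)
  if (n %% 3 != 0) stop("waters_from_atoms: atom count not a multiple of 3")
  out <- list()
  for (k in seq_len(n / 3)) {
    i <- 3 * (k - 1) + 1
    if (toupper(species[i]) != "O" || toupper(species[i + 1]) != "H" ||
        toupper(species[i + 2]) != "H") {
      stop("waters_from_atoms: expected O,H,H triplet at atom ", i)
    }
    out[[k]] <- list(O = coords[i, ], H1 = coords[i + 1, ],
                     H2 = coords[i + 2, ])
  }
  out
}

#' Radially deform a cage of rigid waters around a subsystem
#'
#' Each water's oxygen moves radially away from (dR > 0) or toward (dR < 0)
#' the geometric center of the subsystem nuclei by `dR`; the hydrogens are
#' rigidly translated with their oxygen, so every intramolecular distance
#' and angle is exactly preserved.
#'
#' @param subsystem_nuclei m x 3 matrix of nuclear positions (same length
#'   unit as the waters; conventionally Angstrom)
#' @param waters list of waters as from [waters_from_atoms()]
#' @param dR scalar radial shift, same unit as the coordinates
#' @return deformed list of waters
#' @export
deform_cage <- function(subsystem_nuclei, waters, dR) {
  subsystem_nuclei <- as.matrix(subsystem_nuclei)
  if (nrow(subsystem_nuclei) < 1) stop("deform_cage: no subsystem nuclei")
  if (length(waters) < 1) stop("deform_cage: no waters")
  C <- colMeans(subsystem_nuclei)
  lapply(waters, function(w) {
    v <- w$O - C
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) stop("deform_cage: oxygen coincides with cage center")
    shift <- dR * v / nv
    list(O = w$O + shift, H1 = w$H1 + shift, H2 = w$H2 + shift)
  })
}

# rigid TIP4P water geometry (Angstrom / degrees)
TIP4P_ROH_ANGSTROM <- 0.9572
TIP4P_HOH_DEG <- 104.52

# canonical water in Angstrom: O at origin, bisector along +z
canonical_water <- function() {
  h <- TIP4P_HOH_DEG / 2 * pi / 180
  list(O = c(0, 0, 0),
       H1 = TIP4P_ROH_ANGSTROM * c(sin(h), 0, cos(h)),
       H2 = TIP4P_ROH_ANGSTROM * c(-sin(h), 0, cos(h)))
}

random_rotation <- function() {
  repeat {
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    if (abs(det(Q) - 1) < 1e-8) return(Q)
  }
}

#' Generate a synthetic spherical cage of rigid waters
#'
#' Emulates a first solvation shell for fixture-scale studies: `n_waters`
#' rigid TIP4P-geometry waters (r_OH = 0.9572 Angstrom, HOH = 104.52
#' degrees) with oxygens on the sphere of radius `inner_radius`, random
#' orientations, pairwise O-O distance > 2.4 Angstrom, reproducible by
#' seed.
#'
#' @param n_waters number of waters (>= 1)
#' @param inner_radius sphere radius, Angstrom
#' @param seed integer RNG seed
#' @param max_attempts placement attempts per water before giving up
#' @return list of waters (`O`, `H1`, `H2` in Angstrom)
#' @export
generate_fixture_cage <- function(n_waters, inner_radius, seed,
                                  max_attempts = 2000) {
  stopifnot(n_waters >= 1, inner_radius > 0)
  set.seed(as.integer(seed))
  os <- matrix(NA_real_, n_waters, 3)
  placed <- 0
  attempts <- 0
  while (placed < n_waters) {
    attempts <- attempts + 1
    if (attempts > max_attempts * n_waters) {
      stop("generate_fixture_cage: packing failed; increase inner_radius")
    }
    u <- stats::rnorm(3)
    pos <- inner_radius * u / sqrt(sum(u^2))
    ok <- placed == 0 ||
      all(sqrt(rowSums((os[seq_len(placed), , drop = FALSE] -
                          matrix(pos, placed, 3, byrow = TRUE))^2)) > 2.4)
    if (ok) {
      placed <- placed + 1
      os[placed, ] <- pos
    }
  }
  lapply(seq_len(n_waters), function(i) {
    R <- random_rotation()
    w <- canonical_water()
    list(O = os[i, ],
         H1 = os[i, ] + drop(R %*% w$H1),
         H2 = os[i, ] + drop(R %*% w$H2))
  })
}

#' Convert a list of waters from Angstrom to bohr
#' @param waters list of waters (Angstrom)
#' @return the same list in bohr
#' @export
waters_to_bohr <- function(waters) {
  lapply(waters, function(w) lapply(w, angstrom_to_bohr))
}
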