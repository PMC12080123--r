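#' Unit conversion constants
#'
#' All internal computation uses Hartree atomic units. Geometry files (XYZ)
#' are in Angstrom and converted on input; analysis results are reported in
#' both hartree and meV.
#'
#' @name units
#' @keywords internal
NULL

#' Bohr per Angstrom
#' @export
BOHR_PER_ANGSTROM <- 1.8897259886

#' milli-electronvolt per hartree
#' @export
MEV_PER_HARTREE <- 27211.386245988

#' Convert Angstrom to bohr
#' @param x length(s) in Angstrom
#' @return length(s) in bohr
#' @export
angstrom_to_bohr <- function(x) x * BOHR_PER_ANGSTROM

#' Convert bohr to Angstrom
#' @param x length(s) in bohr
#' @return length(s) in Angstrom
#' @export
bohr_to_angstrom <- function(x) x / BOHR_PER_ANGSTROM

#' Convert hartree to meV
#' @param x energy in hartree
#' @return energy in meV
#' @export
hartree_to_mev <- function(x) x * MEV_PER_HARTREE

#' Convert meV to hartree
#' @param x energy in meV
#' @return energy in hartree
#' @export
mev_to_hartree <- function(x) x / MEV_PER_HARTREE
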