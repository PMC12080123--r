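#' @title Observables from raw QMC energies
#' @description Supermolecular interaction energies, solvation energies and
#'   the environment-induced binding-energy change, with quadrature
#'   uncertainty propagation; plus a PES/solvation scan driver with an
#'   overpolarization (variance blow-up) diagnostic.
#' @name analysis
NULL

# signed combination of energy_estimate objects with quadrature errors
combine_estimates <- function(ests, signs) {
  stopifnot(length(ests) == length(signs))
  cfgs <- lapply(ests, function(e) e$config)
  have <- !vapply(cfgs, is.null, TRUE)
  if (sum(have) >= 2) {
    ref <- cfgs[have][[1]]
    for (cc in cfgs[have][-1]) {
      same <- identical(cc[order(names(cc))], ref[order(names(ref))])
      if (!same) {
        diffs <- unique(c(names(ref)[!vapply(names(ref), function(k)
          identical(ref[[k]], cc[[k]]), TRUE)],
          setdiff(names(cc), names(ref))))
        stop("inconsistent run configurations; differing fields: ",
             paste(diffs, collapse = ", "))
      }
    }
  }
  m <- sum(signs * vapply(ests, `[[`, 0, "mean"))
  se <- sqrt(sum(vapply(ests, `[[`, 0, "stderr")^2))
  out <- energy_estimate(mean = m, stderr = se, variance = NA_real_,
                         n_eff = NA_real_,
                         n_samples = sum(vapply(ests, `[[`, 0, "n_samples")))
  if (any(have)) out$config <- cfgs[have][[1]]
  out
}

#' Supermolecular interaction energy
#'
#' E_int = E_AB - E_A - E_B with quadrature error propagation. Runs must
#' share the model configuration (damping kernel, sigma, ansatz family);
#' estimates carrying a `config` field are checked and mismatches refused.
#'
#' @param E_AB,E_A,E_B [energy_estimate()]s for the dimer and the monomers
#' @return an [energy_estimate()] (mean/stderr in hartree)
#' @export
interaction_energy <- function(E_AB, E_A, E_B) {
  combine_estimates(list(E_AB, E_A, E_B), c(1, -1, -1))
}

#' Solvation energy
#'
#' E_solv = E(subsystem + environment) - E(subsystem) - E(environment).
#'
#' @param E_sub_plus_env,E_sub,E_env [energy_estimate()]s
#' @return an [energy_estimate()]
#' @export
solvation_energy <- function(E_sub_plus_env, E_sub, E_env) {
  combine_estimates(list(E_sub_plus_env, E_sub, E_env), c(1, -1, -1))
}

#' Environment-induced binding-energy change
#'
#' Delta E_b = E_solv(dimer) - E_solv(monomer 1) - E_solv(monomer 2): the
#' change of the dimer binding energy caused by the environment, from the
#' three solvation energies at the same cage deformation.
#'
#' @param E_solv_D,E_solv_M1,E_solv_M2 [energy_estimate()]s (same
#'   environment, same deformation dR; `config$dR` mismatches are refused)
#' @return an [energy_estimate()]
#' @export
binding_energy_change <- function(E_solv_D, E_solv_M1, E_solv_M2) {
  drs <- lapply(list(E_solv_D, E_solv_M1, E_solv_M2),
                function(e) e$config$dR)
  have <- !vapply(drs, is.null, TRUE)
  if (sum(have) >= 2 &&
      max(abs(diff(unlist(drs[have])))) > 1e-12) {
    stop("binding_energy_change: inputs computed at different dR")
  }
  combine_estimates(list(E_solv_D, E_solv_M1, E_solv_M2), c(1, -1, -1))
}

#' Scan a potential-energy surface over a geometry grid
#'
#' Dispatches one QMC run per grid point (separation R or cage deformation
#' dR), collects energies with error bars and flags points whose
#' local-energy variance exceeds `blowup_factor` times the scan median —
#' the operational overpolarization diagnostic: a bare-Coulomb scan blows
#' up at short range while a damped scan stays quiet.
#'
#' @param grid numeric vector of separations / deformations
#' @param system_fn function(g) -> [el_qdo_system()] for grid value g
#' @param params_fn function(system) -> [ansatz_parameters()]
#' @param method `"vmc"` or `"dmc"`
#' @param settings a [vmc_settings()] or [dmc_settings()] matching `method`
#' @param seed base seed; point i runs with seed + i (independent seeds
#'   per point; errors combine in quadrature downstream)
#' @param blowup_factor variance threshold relative to the scan median
#' @return data.frame of class `pes_scan` with columns `x`, `energy`,
#'   `stderr` (hartree), `energy_mev`, `stderr_mev`, `variance`,
#'   `unstable`, `failed`
#' @export
pes_scan <- function(grid, system_fn, params_fn, method = c("vmc", "dmc"),
                     settings = NULL, seed = 1, blowup_factor = 10) {
  method <- match.arg(method)
  if (is.null(settings)) {
    settings <- if (method == "vmc") vmc_settings() else dmc_settings()
  }
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    g <- grid[i]
    res <- tryCatch({
      sys <- system_fn(g)
      par <- params_fn(sys)
      s <- settings
      s$seed <- as.integer(seed + i)
      est <- if (method == "vmc") run_vmc(par, sys, s) else
        run_dmc(par, sys, s)
      data.frame(x = g, energy = est$mean, stderr = est$stderr,
                 variance = est$variance, failed = FALSE)
    }, error = function(e) {
      warning(sprintf("pes_scan: point %g failed: %s", g,
                      conditionMessage(e)))
      data.frame(x = g, energy = NA_real_, stderr = NA_real_,
                 variance = NA_real_, failed = TRUE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  med <- stats::median(out$variance, na.rm = TRUE)
  out$unstable <- !is.na(out$variance) & med > 0 &
    out$variance > blowup_factor * med
  out$unstable[out$failed] <- TRUE
  out$energy_mev <- hartree_to_mev(out$energy)
  out$stderr_mev <- hartree_to_mev(out$stderr)
  class(out) <- c("pes_scan", "data.frame")
  attr(out, "method") <- method
  attr(out, "blowup_factor") <- blowup_factor
  out
}

#' Write a PES scan to CSV and JSON
#'
#' @param scan a [pes_scan()] result
#' @param csv,json output paths (either may be `NULL` to skip)
#' @return invisibly, the scan
#' @export
write_pes <- function(scan, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(as.data.frame(scan), csv,
                                      row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(method = attr(scan, "method"),
                              points = as.data.frame(scan)),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(scan)
}

#' Plot a PES scan
#'
#' Energy (meV) against the grid coordinate with error bars; unstable
#' (variance blow-up) points are highlighted.
#'
#' @param x a `pes_scan`
#' @param ... unused
#' @return a ggplot object
#' @export
plot.pes_scan <- function(x, ...) {
  # aes() data-masked columns: x, energy_mev, ymin, ymax, unstable
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot.pes_scan needs ggplot2")
  }
  df <- as.data.frame(x)[!x$failed, ]
  df$ymin <- df$energy_mev - df$stderr_mev
  df$ymax <- df$energy_mev + df$stderr_mev
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = energy_mev)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ymin, ymax = ymax),
                           width = 0) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = unstable)) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "black", `TRUE` = "red"),
      name = "variance blow-up") +
    ggplot2::labs(x = "separation / deformation", y = "energy (meV)")
}
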