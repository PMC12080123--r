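#' Build a system and ansatz from a YAML run configuration
#'
#' Configuration schema (all geometry files in Angstrom, converted
#' internally to bohr):
#' \preformatted{
#' system:
#'   nuclei: [{position: [x,y,z], Z: 1}, ...]        # bohr
#'   n_up: 1
#'   n_down: 0
#'   qdos: [{species: Ar, center: [x,y,z]}, ...]     # bohr; or explicit
#'          {center:, q:, mu:, omega:, sigma:}
#'   waters_xyz: cage.xyz                            # O,H,H triplets
#'   point_charges: [{position:, charge:, parent:}]
#'   damping: erf
#'   sigma: 0.5
#' ansatz:
#'   orbitals: orbitals.json        # or
#'   hydrogen_1s: {nucleus: 1, zeta: 1.0}
#' method: vmc                      # or dmc
#' vmc: {n_steps: 500, n_walkers: 100, seed: 1}
#' dmc: {dtau: 0.005, target_population: 100, n_blocks: 50,
#'       steps_per_block: 50, seed: 1}
#' }
#'
#' @param config path to a YAML file, or an equivalent nested list
#' @param base_dir directory for relative file references (defaults to the
#'   config file's directory)
#' @return list with `system`, `params`, `method`, `settings`
#' @export
load_run_config <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(base_dir)) base_dir <- "."
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  sc <- config$system
  if (is.null(sc)) stop("load_run_config: missing system block")
  nuclei <- lapply(sc$nuclei, function(n) nucleus(unlist(n$position), n$Z))
  qdos <- lapply(sc$qdos, function(q) {
    if (!is.null(q$species)) {
      p <- qdo_params(q$species)
      qdo_spec(unlist(q$center), p$q, p$mu, p$omega,
               sigma = if (is.null(q$sigma)) NA_real_ else q$sigma)
    } else {
      qdo_spec(unlist(q$center), q$q, q$mu, q$omega,
               sigma = if (is.null(q$sigma)) NA_real_ else q$sigma)
    }
  })
  pcs <- lapply(sc$point_charges, function(p) {
    point_charge(unlist(p$position), p$charge,
                 parent = if (is.null(p$parent)) NA_integer_ else p$parent)
  })
  if (!is.null(sc$waters_xyz)) {
    xyz <- read_xyz(resolve(sc$waters_xyz))
    waters <- waters_to_bohr(waters_from_atoms(xyz$species, xyz$coords))
    env <- waters_to_environment(waters)
    off <- length(qdos)
    env$point_charges <- lapply(env$point_charges, function(p) {
      p$parent <- p$parent + off
      p
    })
    qdos <- c(qdos, env$qdos)
    pcs <- c(pcs, env$point_charges)
  }
  system <- el_qdo_system(
    nuclei = nuclei,
    n_up = if (is.null(sc$n_up)) 0L else sc$n_up,
    n_down = if (is.null(sc$n_down)) 0L else sc$n_down,
    qdos = qdos, point_charges = pcs,
    damping = if (is.null(sc$damping)) "erf" else sc$damping,
    sigma = if (is.null(sc$sigma)) 0.5 else sc$sigma)
  an <- config$ansatz
  mo <- NULL
  if (!is.null(an$orbitals)) {
    mo <- read_orbitals(resolve(an$orbitals), nuclei = nuclei)
  } else if (!is.null(an$hydrogen_1s)) {
    h <- an$hydrogen_1s
    idx <- if (is.null(h$nucleus)) 1L else h$nucleus
    mo <- hydrogen_1s(nuclei[[idx]]$position,
                      zeta = if (is.null(h$zeta)) 1 else h$zeta)
  }
  params <- ansatz_parameters(system, mo = mo)
  method <- if (is.null(config$method)) "vmc" else config$method
  settings <- if (method == "vmc") {
    do.call(vmc_settings, if (is.null(config$vmc)) list() else config$vmc)
  } else {
    do.call(dmc_settings, if (is.null(config$dmc)) list() else config$dmc)
  }
  list(system = system, params = params, method = method,
       settings = settings)
}

#' Run a QMC calculation from a YAML configuration
#'
#' @inheritParams load_run_config
#' @param log_jsonl optional path; per-block estimator records are appended
#'   as JSON lines
#' @return an [energy_estimate()]
#' @export
run_from_config <- function(config, base_dir = NULL, log_jsonl = NULL) {
  rc <- load_run_config(config, base_dir)
  est <- if (rc$method == "vmc") {
    run_vmc(rc$params, rc$system, rc$settings, keep_series = TRUE)
  } else {
    run_dmc(rc$params, rc$system, rc$settings, keep_series = TRUE)
  }
  if (!is.null(log_jsonl)) {
    series <- if (rc$method == "vmc") est$series else est$block_energies
    con <- file(log_jsonl, "w")
    on.exit(close(con))
    for (i in seq_along(series)) {
      writeLines(jsonlite::toJSON(
        list(block = i, energy = series[i]), auto_unbox = TRUE,
        digits = NA), con)
    }
  }
  est$state <- NULL
  est
}

#' Save / restore a walker population checkpoint (JSON)
#'
#' @param state population state (`Xe`, `Xd` arrays)
#' @param path JSON file
#' @return `write_checkpoint` the path invisibly; `read_checkpoint` the
#'   state
#' @export
write_checkpoint <- function(state, path) {
  enc <- list(
    Xe = if (!is.null(state$Xe)) list(dim = dim(state$Xe),
                                      data = as.numeric(state$Xe)),
    Xd = if (!is.null(state$Xd)) list(dim = dim(state$Xd),
                                      data = as.numeric(state$Xd)))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  j <- jsonlite::fromJSON(path)
  dec <- function(e) {
    if (is.null(e) || length(e) == 0) return(NULL)
    array(e$data, dim = e$dim)
  }
  list(Xe = dec(j$Xe), Xd = dec(j$Xd))
}
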