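# Run configuration: a single validated YAML tree with CLI overrides.

.config_schema <- list(
  molecule = c("xyz", "xyz_file", "charge", "multiplicity"),
  basis = NULL,
  cas = c("n_elec", "n_orb", "indices"),
  driver = NULL,
  mapping = NULL,
  canonical = NULL,
  optimizer = c("method", "maxit", "a", "c", "alpha", "gamma", "A",
                "calibrate", "target_step"),
  noise = c("depolarizing_1q", "depolarizing_2q", "readout_flip", "shots"),
  casscf = c("energy_tol", "gradient_tol", "max_macro"),
  hea_layers = NULL,
  seed = NULL,
  repeats = NULL,
  fcidump = NULL,
  output = c("trace_csv", "stats_csv")
)

#' Default run configuration
#' @return nested list with every supported key and its default.
#' @export
default_config <- function() {
  list(
    molecule = list(xyz = NULL, xyz_file = NULL, charge = 0L,
                    multiplicity = 1L),
    basis = "sto-3g",
    cas = list(n_elec = 2L, n_orb = 2L, indices = NULL),
    driver = "FCI",
    mapping = "jw",
    canonical = TRUE,
    optimizer = list(method = NULL, maxit = NULL),
    noise = NULL,
    casscf = list(energy_tol = 1e-8, gradient_tol = 1e-5, max_macro = 200L),
    hea_layers = 1L,
    seed = 1L,
    repeats = 20L,
    fcidump = NULL,
    output = list(trace_csv = NULL, stats_csv = NULL)
  )
}

.merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- .merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, validates every key against the schema (unknown keys
#' are rejected), and fills unset keys from [default_config()].
#'
#' @param path YAML config file, or NULL for pure defaults.
#' @param overrides named list merged on top (e.g. from CLI flags).
#' @return validated config list of class `qc_run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (key in names(user)) {
      if (!key %in% names(.config_schema)) {
        stop("unknown config key: ", key)
      }
      sub <- .config_schema[[key]]
      if (!is.null(sub) && is.list(user[[key]])) {
        bad <- setdiff(names(user[[key]]), sub)
        if (length(bad)) {
          stop("unknown config key: ", key, ".", bad[1])
        }
      }
    }
    cfg <- .merge_config(cfg, user)
  }
  if (length(overrides)) cfg <- .merge_config(cfg, overrides)
  structure(cfg, class = c("qc_run_config", "list"))
}

#' Materialize configured objects
#'
#' Builds geometry, integrals, SCF, noise and optimizer objects from a
#' validated configuration.
#'
#' @param cfg a `qc_run_config`.
#' @return list: `geom`, `ints`, `scf`, `act_spec`, `noise`, `optimizer`,
#'   `crit`.
#' @export
realize_config <- function(cfg) {
  geom <- NULL; ints <- NULL; scf <- NULL
  if (!is.null(cfg$fcidump)) {
    # pure active-space run from an FCIDUMP file
  } else {
    txt <- if (!is.null(cfg$molecule$xyz_file)) {
      readLines(cfg$molecule$xyz_file)
    } else if (!is.null(cfg$molecule$xyz)) cfg$molecule$xyz else
      stop("config requires molecule.xyz, molecule.xyz_file, or fcidump")
    geom <- parse_xyz(txt, charge = cfg$molecule$charge %||% 0L,
                      multiplicity = cfg$molecule$multiplicity %||% 1L)
    ints <- compute_ao_integrals(geom, cfg$basis)
    scf <- run_hf(ints)
  }
  noise <- if (!is.null(cfg$noise)) {
    do.call(noise_spec, cfg$noise)
  } else NULL
  method <- cfg$optimizer$method %||%
    (if (!is.null(noise)) "SPSA" else "BFGS")
  opt_args <- cfg$optimizer[!vapply(cfg$optimizer, is.null, logical(1))]
  opt_args$method <- method
  optimizer <- do.call(optimizer_spec, opt_args)
  act_spec <- list(n_elec = cfg$cas$n_elec, n_orb = cfg$cas$n_orb,
                   indices = cfg$cas$indices)
  crit <- convergence_criteria(cfg$casscf$energy_tol, cfg$casscf$gradient_tol,
                               cfg$casscf$max_macro)
  list(geom = geom, ints = ints, scf = scf, act_spec = act_spec,
       noise = noise, optimizer = optimizer, crit = crit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
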