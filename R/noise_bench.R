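# Noisy quantum-CASSCF benchmark harness: repeated runs of the
# HEA + SPSA + parity-reduced pipeline under the parameterized noise model,
# canonical vs noncanonical active orbitals, per-iteration statistics.

#' Configuration for a noisy quantum-CASSCF benchmark
#'
#' @param ints a `qc_ao_integrals`.
#' @param act_spec active-space spec as in [run_casscf()].
#' @param noise a `qc_noise_spec` (NULL for the noiseless limit with exact
#'   expectations).
#' @param canonical canonicalize active orbitals each macro-iteration.
#' @param max_macro macro-iteration cap (benchmark default 9).
#' @param energy_tol loose energy convergence threshold.
#' @param hea_layers HEA entangling-layer count.
#' @param spsa SPSA [optimizer_spec()].
#' @param scf optional precomputed `qc_scf`.
#' @return list of class `qc_bench_config`.
#' @export
bench_config <- function(ints, act_spec, noise = default_noise(),
                         canonical = TRUE, max_macro = 9L,
                         energy_tol = 1e-5, hea_layers = 1L,
                         spsa = optimizer_spec("SPSA", maxit = 60L),
                         scf = NULL) {
  structure(list(ints = ints, act_spec = act_spec, noise = noise,
                 canonical = canonical, max_macro = as.integer(max_macro),
                 energy_tol = energy_tol, hea_layers = as.integer(hea_layers),
                 spsa = spsa, scf = scf), class = "qc_bench_config")
}

# single noisy (or noiseless) quantum CASSCF run, fixed seed
.bench_single <- function(config, seed) {
  noisy <- !is.null(config$noise)
  vqe_opts <- list(
    optimizer = config$spsa, seed = seed, hea_layers = config$hea_layers
  )
  if (noisy) {
    noise <- config$noise
    vqe_opts$make_evaluator <- function(h, spec) {
      force(h); force(spec)
      function(params) {
        noisy_estimator(hea_gates(params, spec), spec$n_qubits, noise)(h)
      }
    }
    vqe_opts$make_rdm_estimator <- function(params, spec) {
      noisy_estimator(hea_gates(params, spec), spec$n_qubits, noise)
    }
  }
  run_casscf(config$ints, config$act_spec, driver = "HEA-VQE",
             crit = convergence_criteria(energy_tol = config$energy_tol,
                                         gradient_tol = 1e-5,
                                         max_macro = config$max_macro),
             encoding = "parity", canonical = config$canonical,
             scf = config$scf, vqe_opts = vqe_opts, noisy = noisy)
}

#' Repeated noisy quantum-CASSCF runs
#'
#' Executes the configuration `n_repeats` times with seeds
#' `base_seed + 0 .. n_repeats - 1`; runs converging before `max_macro`
#' iterations are padded by carrying their last energy forward so that
#' per-iteration statistics are over a rectangular energy matrix.
#'
#' @param config a [bench_config()].
#' @param n_repeats number of repeats (>= 2).
#' @param base_seed integer seed base.
#' @return object of class `qc_bench_stats`: `energies` (n_repeats x
#'   max_macro), per-iteration `mean`, `sd`, `ci95` (1.96 sd / sqrt(n)),
#'   `min_average_energy`, `avg_sd` and `avg_ci` over all data points, and
#'   the two aggregation variants `avg_sd_over_iterations` /
#'   `sd_over_all_points`.
#' @export
run_repeated <- function(config, n_repeats, base_seed = 1L) {
  if (n_repeats < 2) stop("n_repeats must be >= 2 for dispersion statistics")
  E <- matrix(NA_real_, n_repeats, config$max_macro)
  for (i in seq_len(n_repeats)) {
    res <- .bench_single(config, seed = base_seed + i - 1L)
    e <- res$trace$energy
    if (length(e) < config$max_macro) {
      e <- c(e, rep(e[length(e)], config$max_macro - length(e)))
    }
    E[i, ] <- e[seq_len(config$max_macro)]
  }
  m <- colMeans(E)
  s <- apply(E, 2, stats::sd)
  ci <- 1.96 * s / sqrt(n_repeats)
  structure(list(
    energies = E, mean = m, sd = s, ci95 = ci,
    n_repeats = n_repeats,
    min_average_energy = min(m),
    avg_sd_over_iterations = mean(s),
    sd_over_all_points = stats::sd(as.vector(E)),
    avg_sd = mean(s), avg_ci = mean(ci)
  ), class = "qc_bench_stats")
}

#' Compare canonical vs noncanonical orbital handling under noise
#'
#' The two configurations must differ only in the `canonical` flag. Both are
#' run `n_repeats` times from the same seed base, and the summary mirrors the
#' minimum-average-energy / averaged-dispersion benchmark table layout.
#'
#' @param config_a,config_b [bench_config()] objects.
#' @param n_repeats repeats per configuration.
#' @param base_seed seed base shared by both runs.
#' @return list of class `qc_bench_report`: `canonical`, `noncanonical`
#'   (`qc_bench_stats`), and `table` (a data.frame summary).
#' @export
compare_canonical <- function(config_a, config_b, n_repeats, base_seed = 1L) {
  fields <- setdiff(names(config_a), c("canonical"))
  for (f in fields) {
    if (!identical(config_a[[f]], config_b[[f]])) {
      stop("configurations differ in '", f, "'; only the canonical flag may differ")
    }
  }
  if (identical(config_a$canonical, config_b$canonical)) {
    stop("configurations have the same canonical flag")
  }
  can <- if (config_a$canonical) config_a else config_b
  non <- if (config_a$canonical) config_b else config_a
  s_can <- run_repeated(can, n_repeats, base_seed)
  s_non <- run_repeated(non, n_repeats, base_seed)
  tab <- data.frame(
    method = c("canonical", "noncanonical"),
    min_average_energy = c(s_can$min_average_energy, s_non$min_average_energy),
    avg_sd = c(s_can$avg_sd, s_non$avg_sd),
    avg_ci95 = c(s_can$avg_ci, s_non$avg_ci)
  )
  structure(list(canonical = s_can, noncanonical = s_non, table = tab),
            class = "qc_bench_report")
}

#' @export
print.qc_bench_stats <- function(x, ...) {
  cat(sprintf("Noisy benchmark: %d repeats x %d iterations\n",
              x$n_repeats, length(x$mean)))
  cat(sprintf("  min average energy: %.6f Ha\n", x$min_average_energy))
  cat(sprintf("  avg sd: %.6f   avg 95%% CI: %.6f\n", x$avg_sd, x$avg_ci))
  invisible(x)
}

#' @export
print.qc_bench_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
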