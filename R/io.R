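#' Serialization: traces, descriptor tables, configs and run manifests
#'
#' Traces are written as CSV with a `time_s` column, one column per species
#' (molecule counts), then `Ca_uM`, `cGMP_uM`, `deltaJ_norm`. Descriptor
#' tables are TSV with columns `genotype`, `strength_Rstar`, `tsat_s`,
#' `tau_rec_s`, `tau_d_s`, `tau_d_norm`. Run configurations are YAML with a
#' versioned schema, and every output can be traced to a run manifest.
#'
#' @name cli_and_io
NULL

#' Write a response trace to CSV
#'
#' @param trace A `response_trace` with species columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  sp <- intersect(rod_species_names(), names(trace))
  out <- data.frame(time_s = trace$time, trace[sp], check.names = FALSE)
  out$Ca_uM <- trace$Ca_uM
  out$cGMP_uM <- trace$cGMP_uM
  out$deltaJ_norm <- trace$deltaJ
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a descriptor table to TSV
#'
#' @param tbl Data frame of descriptors.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_descriptor_tsv <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML schema (version 1):
#' ```yaml
#' schema: 1
#' profile: amphibian
#' mutant: {RK: 2.4, RGS: 1.0}
#' switches: {oligomerization_off: false}
#' protocol: {kind: flash, strength_Rstar: 118000, duration_s: 0.024}
#' horizon_s: 60
#' ```
#'
#' @param path YAML file path.
#' @return List with `params`, `mutant` ([mutant_spec()]), `protocol`
#'   ([stimulus_protocol()]) and `horizon`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$schema) && cfg$schema != 1)
    stop("unsupported config schema version: ", cfg$schema, call. = FALSE)
  profile <- cfg$profile %||% "amphibian"
  if (!identical(profile, "amphibian"))
    stop("unknown parameter profile: ", profile, call. = FALSE)
  params <- default_params(overrides = cfg$overrides %||% list())
  sw <- cfg$switches %||% list()
  mut <- do.call(mutant_spec, c(
    lapply(cfg$mutant %||% list(), as.numeric),
    list(oligomerization_off = isTRUE(sw$oligomerization_off),
         omega_Arr = as.numeric(sw$omega_Arr %||% 0))))
  pr <- cfg$protocol %||% list()
  protocol <- stimulus_protocol(
    kind = pr$kind %||% "flash",
    strength = as.numeric(pr$strength_Rstar %||%
                            stop("config is missing field protocol.strength_Rstar",
                                 call. = FALSE)),
    flash_duration = as.numeric(pr$duration_s %||% params$flash_duration),
    step_duration = as.numeric(pr$step_duration_s %||% 60),
    onset = as.numeric(pr$onset_s %||% 1),
    background = as.numeric(pr$background_Rstar_s %||% 0))
  list(params = params, mutant = mut, protocol = protocol,
       horizon = as.numeric(cfg$horizon_s %||%
                              (if ((pr$kind %||% "flash") == "flash") 60 else 90)))
}

#' Build a run manifest
#'
#' Records the configuration snapshot, a parameter-set hash, solver
#' tolerances, dark-state and conservation residuals, and output paths, so
#' every output file is traceable.
#'
#' @param network The `rod_network` that was run.
#' @param trace The resulting `response_trace`.
#' @param outputs Character vector of output file paths.
#' @param rtol,atol Solver tolerances used.
#' @return Manifest list (serializable with [yaml::write_yaml()]).
#' @export
run_manifest <- function(network, trace, outputs, rtol = 1e-8, atol = 1e-12) {
  f <- build_derivatives(network)
  y0 <- initial_state(network)
  dark_resid <- max(abs(f(0, y0)) / pmax(abs(y0), 1))
  cons <- conservation_residuals(network, trace)
  list(
    schema = 1,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    parameter_hash = param_hash(network$params),
    solver = list(method = "lsoda", rtol = rtol, atol = atol),
    dark_state_residual = dark_resid,
    conservation_residuals = as.list(cons),
    outputs = as.list(outputs)
  )
}

param_hash <- function(params) {
  s <- paste(names(params),
             vapply(params, function(x) paste(format(x, digits = 17), collapse = ","),
                    character(1)),
             sep = "=", collapse = ";")
  # small polynomial rolling hash over the serialized parameter string
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
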