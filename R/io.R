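#' Experiment configuration
#'
#' A plain-list configuration resolvable to a concrete run plan, round-trips
#' through YAML. Defaults reproduce the package's standard settings.
#'
#' @param architecture `"core"` or `"comprehensive"`.
#' @param genotype Either a preset name (`"core_showcase"`,
#'   `"comprehensive_showcase"`) or a named list of genotype parameters.
#' @param n_steps,dt,noise_scale,seed Simulation settings.
#' @param left_frac,right_frac Input fractions.
#' @param actuators Named list of [actuator_params()] overrides.
#' @param omega_threshold Segmentation threshold (rad/ms).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(architecture = "core", genotype = "core_showcase",
                              n_steps = LAL_N_STEPS, dt = LAL_DT,
                              noise_scale = LAL_NOISE_SCALE, seed = 1L,
                              left_frac = 0.5, right_frac = 0.5,
                              actuators = list(), omega_threshold = LAL_OMEGA_THRESHOLD) {
  if (!architecture %in% c("core", "comprehensive"))
    abort("architecture must be 'core' or 'comprehensive'")
  structure(list(architecture = architecture, genotype = genotype,
                 n_steps = n_steps, dt = dt, noise_scale = noise_scale,
                 seed = seed, left_frac = left_frac, right_frac = right_frac,
                 actuators = actuators, omega_threshold = omega_threshold),
            class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns an `experiment_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

#' @rdname read_config
#' @param config An [experiment_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Resolve a configured genotype
#'
#' @param config An [experiment_config()].
#' @return A one-row genotype tibble.
#' @export
resolve_genotype <- function(config) {
  g <- config$genotype
  if (is.character(g)) {
    presets <- list(core_showcase = core_showcase,
                    comprehensive_showcase = comprehensive_showcase)
    if (!g %in% names(presets))
      abort(paste0("unknown preset '", g, "'; available: ",
                   paste(names(presets), collapse = ", ")))
    presets[[g]]()
  } else {
    as_tibble(g)
  }
}

# One comment block describing provenance, prefixed to every output file.
.provenance_header <- function(config, comment = "#") {
  fields <- unlist(lapply(unclass(config), function(x)
    paste(format(x, digits = 15), collapse = " ")))
  c(paste(comment, "lalcpg", as.character(utils::packageVersion("lalcpg"))),
    paste0(comment, " ", names(fields), ": ", fields))
}

#' Write a table as CSV with a provenance header
#'
#' The header echoes every configuration field (commented lines), so the file
#' is regenerable from its own metadata.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param config The [experiment_config()] that produced `df`.
#' @return `path`, invisibly.
#' @export
write_table_with_provenance <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(config), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed CSV
#'
#' @param path File path.
#' @return A tibble (header lines skipped).
#' @export
read_provenance_table <- function(path) {
  as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Write spike trains as JSON
#'
#' @param sim An `snn_sim`.
#' @param path Output path.
#' @param config Optional config echoed under `$provenance`.
#' @return `path`, invisibly.
#' @export
write_spikes_json <- function(sim, path, config = NULL) {
  payload <- list(spikes = sim$spikes)
  if (!is.null(config)) payload$provenance <- unclass(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
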