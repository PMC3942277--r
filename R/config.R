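# Configuration loading, validation and serialization (YAML).

#' Load and validate a model configuration
#'
#' Reads a YAML configuration with one top-level block per input domain
#' (event rates, treatment effects, mortality, utilities, costs, persistence,
#' settings), validates it with [validate_parameters()] and returns the
#' parameter set. Validation errors name the offending field path.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `afcea_parameters` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) afcea_stop(path, "configuration file not found")
  raw <- yaml::read_yaml(path)
  raw$settings$wtp_grid <- as.numeric(unlist(raw$settings$wtp_grid))
  raw$mortality$life_table$ages <- as.numeric(unlist(raw$mortality$life_table$ages))
  raw$mortality$life_table$qx <- as.numeric(unlist(raw$mortality$life_table$qx))
  validate_parameters(raw)
}

#' Serialize a parameter set to YAML
#'
#' Writes the full parameter set at full precision so that a load-serialize-
#' load round trip reproduces every value exactly.
#'
#' @param params A validated parameter set.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  x <- unclass(params)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' The bundled base-case parameter set
#'
#' Loads the packaged base-case configuration: trial event rates and relative
#' risks, case-fatality and post-event mortality, literature utilities, 2013
#' Greek payer unit costs and monitoring schedule, trial persistence, and the
#' run settings (3-month cycles, 3.5% annual discount, start age 75, lifetime
#' horizon to age 110, switch to aspirin). The background life table and the
#' second-line event-rate table bundled with it are documented fixtures, not
#' published inputs; see [default_life_table()] and
#' [secondline_event_rates()].
#'
#' @return A validated `afcea_parameters` object.
#' @export
base_case_parameters <- function() {
  path <- system.file("extdata", "base_case.yaml", package = "afcea",
                      mustWork = TRUE)
  load_config(path)
}
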