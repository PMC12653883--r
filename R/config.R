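## YAML configuration for the command-line entry point: maps a flat YAML
## document onto the settings constructors.

#' Read audit settings from a YAML file
#'
#' Recognized top-level keys: `search` ([search_settings()] fields),
#' `cluster` ([cluster_settings()] fields), `classifier`
#' ([classifier_settings()] fields) and `focal_region`. Missing keys fall
#' back to the defaults.
#'
#' @param file YAML path; `NULL` gives all defaults.
#' @return list with elements `search`, `cluster`, `classifier`,
#'   `focal_region`.
#' @export
read_audit_config <- function(file = NULL) {
  cfg <- if (is.null(file)) list() else yaml::read_yaml(file)
  list(search = do.call(search_settings, cfg$search %||% list()),
       cluster = do.call(cluster_settings, cfg$cluster %||% list()),
       classifier = do.call(classifier_settings, cfg$classifier %||% list()),
       focal_region = cfg$focal_region %||% "VLG")
}

#' Read a simulation configuration from a YAML file
#'
#' Top-level keys are [sim_config()] arguments.
#'
#' @param file YAML path; `NULL` gives all defaults.
#' @param seed optional seed override.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(file = NULL, seed = NULL) {
  cfg <- if (is.null(file)) list() else yaml::read_yaml(file)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  do.call(sim_config, cfg)
}
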