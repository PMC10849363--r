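#' Load a simulation/run configuration from YAML
#'
#' Reads a YAML file whose keys are [sim_config()] arguments; unknown keys
#' are rejected by name, and absent keys take the package defaults.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding the file's value.
#' @return A validated `sim_config`.
#' @export
load_sim_config <- function(path, seed = NULL) {
  vals <- yaml::read_yaml(path) %||% list()
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (!is.null(seed)) vals$seed <- seed
  if (!is.null(vals$chromosome_lengths)) {
    vals$chromosome_lengths <- as.numeric(unlist(vals$chromosome_lengths))
  }
  do.call(sim_config, vals)
}
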