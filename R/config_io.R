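#' Read a scenario configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [scenario_config()]; `seed` is
#' mandatory so a scenario is always reproducible from its file alone.
#'
#' @param path YAML file path.
#' @return a validated `scenario_config`.
#' @export
scenario_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("scenario YAML must set a seed")
  for (nm in c("stress_weights", "env_noise_sd"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  if (!is.null(cfg$years) && length(cfg$years) == 2)
    cfg$years <- cfg$years[1]:cfg$years[2]
  do.call(scenario_config, cfg)
}
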