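#' Read a run configuration from YAML
#'
#' Maps the optional top-level blocks `gas_exchange`, `mcmc`, `priors`, `qc`
#' and `scenario` onto the corresponding configuration constructors; keys not
#' present keep the package defaults.
#'
#' @param path Path to a YAML file.
#' @return List with elements `gas`, `mcmc`, `priors`, `qc`, `scenario`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(block, constructor) {
    args <- raw[[block]]
    if (is.null(args)) return(constructor())
    if (block == "mcmc" && !is.null(args$proposal_sd)) {
      args$proposal_sd <- unlist(args$proposal_sd)
    }
    if (block == "mcmc" && !is.null(args$init)) {
      args$init <- unlist(args$init)
    }
    if (block == "scenario" && !is.null(args$coupling)) {
      args$coupling <- unlist(args$coupling)
    }
    do.call(constructor, args)
  }
  list(gas = build("gas_exchange", gas_exchange_config),
       mcmc = build("mcmc", mcmc_config),
       priors = build("priors", prior_config),
       qc = build("qc", qc_config),
       scenario = build("scenario", scenario_config))
}
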