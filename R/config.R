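#' Read a structured run configuration
#'
#' YAML layout (1-based orbital indices, as in FCIDUMP files):
#' ```yaml
#' gas:
#'   subspaces: [[1, 2], [3, 4], [5, 6]]
#'   flavor: local          # or cumulative
#'   n_min: [0, 0, 0]
#'   n_max: [4, 4, 4]
#' p_space:                 # optional: defines SplitGAS P constraints
#'   n_min: [3, 0, 0]
#'   n_max: [4, 4, 1]
#' dynamics:                # optional: fciqmc_config() fields
#'   target_walkers: 50000
#'   n_steps: 2500
#' ```
#'
#' @param path YAML file.
#' @param n_elec Active electron count (from the integral set).
#' @return List with `gas` (a [gas_partition()]), `part` (a
#'   `split_partitioning` or `NULL`), and `dynamics` (named list).
#' @export
read_run_config <- function(path, n_elec) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_run_config needs the 'yaml' package")
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$gas))
  g <- cfg$gas
  gas <- gas_partition(lapply(g$subspaces, as.integer),
                       n_min = g$n_min, n_max = g$n_max,
                       n_elec_active = n_elec,
                       flavor = if (is.null(g$flavor)) "local" else g$flavor)
  part <- NULL
  if (!is.null(cfg$p_space)) {
    p <- cfg$p_space
    pgas <- gas_partition(gas$subspaces, n_min = p$n_min, n_max = p$n_max,
                          n_elec_active = n_elec,
                          flavor = if (is.null(p$flavor)) "local" else p$flavor)
    part <- build_ip_vector(enumerate_supergroups(gas), pgas)
  }
  list(gas = gas, part = part,
       dynamics = if (is.null(cfg$dynamics)) list() else cfg$dynamics)
}
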