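#' Construct a method configuration
#'
#' Bundles every tunable constant of the pipeline. The defaults are the
#' published operating point of the method; see [TargetingConfig-class] for
#' the meaning of each parameter.
#'
#' @param k proportionality constant between rounded RPKM and the flux bound,
#'   in mmol/gDW/h per RPKM. Default 0.0027 (calibrated against the measured
#'   growth rate of the A549 cell line).
#' @param granularity expression values are rounded up to the next multiple of
#'   this before scaling; default 10 RPKM.
#' @param blockFraction throttled reactions keep this fraction of their
#'   baseline flux; default 0.1.
#' @param singleThreshold a candidate is kept only if the target's relative
#'   growth falls below this; default 0.9.
#' @param selectivityMargin required excess of reference over target relative
#'   growth; default 0.05.
#' @param stopRatio the greedy search stops once target relative growth drops
#'   to this; default 0.5.
#' @param fdrLevel Benjamini-Hochberg level for differential calls; default 0.01.
#' @param solverTolerance LP feasibility/optimality tolerance; default 1e-7.
#' @param seed default RNG seed for stochastic operations.
#' @param rankSigned rank candidates by signed flux difference rather than the
#'   default difference of magnitudes.
#' @return a validated [TargetingConfig-class].
#' @examples
#' cfg <- targetingConfig()
#' cfg
#' @export
targetingConfig <- function(k = 0.0027, granularity = 10, blockFraction = 0.1,
                            singleThreshold = 0.9, selectivityMargin = 0.05,
                            stopRatio = 0.5, fdrLevel = 0.01,
                            solverTolerance = 1e-7, seed = 1L,
                            rankSigned = FALSE) {
  new("TargetingConfig", k = k, granularity = granularity,
      blockFraction = blockFraction, singleThreshold = singleThreshold,
      selectivityMargin = selectivityMargin, stopRatio = stopRatio,
      fdrLevel = fdrLevel, solverTolerance = solverTolerance,
      seed = as.integer(seed), rankSigned = isTRUE(rankSigned))
}

# snake_case keys used in JSON config files (and the CLI)
.configKeys <- c(
  k = "k", granularity = "granularity", block_fraction = "blockFraction",
  single_threshold = "singleThreshold", selectivity_margin = "selectivityMargin",
  stop_ratio = "stopRatio", fdr_level = "fdrLevel",
  solver_tolerance = "solverTolerance", seed = "seed", rank_signed = "rankSigned"
)

#' Read a configuration from JSON
#'
#' Keys are the snake_case field names `k`, `granularity`, `block_fraction`,
#' `single_threshold`, `selectivity_margin`, `stop_ratio`, `fdr_level`,
#' `solver_tolerance`, `seed`, `rank_signed`; absent keys keep their defaults.
#'
#' @param path path to a JSON file.
#' @param overrides named list applied on top of the file's values (used by the
#'   command line's per-key flags).
#' @return a validated [TargetingConfig-class].
#' @export
readTargetingConfig <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) .ioError(sprintf("config file not found: %s", path))
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vals <- utils::modifyList(as.list(vals), as.list(overrides))
  unknown <- setdiff(names(vals), names(.configKeys))
  if (length(unknown))
    .configError(sprintf("unknown config key(s): %s (valid: %s)",
                         paste(unknown, collapse = ", "),
                         paste(names(.configKeys), collapse = ", ")))
  names(vals) <- .configKeys[names(vals)]
  do.call(targetingConfig, vals)
}

.configAsList <- function(config) {
  out <- lapply(stats::setNames(unname(.configKeys), names(.configKeys)),
                function(slotName) slot(config, slotName))
  out
}

#' Provenance hash of a configuration
#'
#' Short stable hash of all configuration fields, recorded in flux-table
#' headers and run manifests so outputs can be traced to the exact settings
#' that produced them.
#'
#' @param config a [TargetingConfig-class].
#' @return an 8-character hexadecimal string.
#' @export
configHash <- function(config) {
  l <- .configAsList(config)
  .fnv1a(paste(names(l), vapply(l, function(v) .fmtNum(as.numeric(v)), character(1)),
               sep = "=", collapse = ";"))
}
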