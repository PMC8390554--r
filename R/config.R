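#' Analysis configuration with study defaults
#'
#' Returns the flat list of thresholds driving the pipeline.  Defaults are the
#' published study settings: 30x minimum coverage, 70% call rate, 50%
#' stable-site fraction, 3-SD PCA outlier rule, replicate correlation floor
#' 0.9, M-value shrinkage factor 1000 (2000 when CpH sites are present),
#' 5% residual-PC variance rule for surrogate selection, 100 IRLS iterations,
#' FDR 0.05, and 20-kb TSS bins.
#'
#' @param ... named overrides of any default.
#' @return named list (class `pdm_config`).
#' @examples
#' cfg <- panelConfig(min_coverage = 20)
#' cfg$min_coverage
#' @export
panelConfig <- function(...) {
  cfg <- list(
    min_coverage     = 30,
    min_call_rate    = 0.7,
    stable_fraction  = 0.5,
    outlier_sd       = 3.0,
    replicate_min_r  = 0.9,
    shrink_factor    = 1000,
    shrink_factor_cph = 2000,
    sv_var_threshold = 0.05,
    irls_max_iter    = 100,
    irls_tol         = 1e-6,
    huber_c          = 1.345,
    fdr_q            = 0.05,
    tss_bin_bp       = 20000,
    quantile_normalize = FALSE,
    pca_outlier_scale  = "beta",
    weight_log_base    = 10,
    rng_seed         = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  stopIfNot(!length(bad), "unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  validateConfig(cfg)
  class(cfg) <- c("pdm_config", "list")
  cfg
}

validateConfig <- function(cfg) {
  pos <- c("min_coverage", "stable_fraction", "outlier_sd", "replicate_min_r",
           "shrink_factor", "shrink_factor_cph", "sv_var_threshold",
           "irls_max_iter", "fdr_q", "tss_bin_bp", "min_call_rate")
  for (f in pos)
    stopIfNot(is.numeric(cfg[[f]]) && cfg[[f]] > 0, "config '%s' must be > 0", f)
  for (f in c("min_call_rate", "stable_fraction", "fdr_q"))
    stopIfNot(cfg[[f]] < 1, "config '%s' must be in (0, 1)", f)
  stopIfNot(cfg$shrink_factor >= 2, "shrink_factor must be >= 2")
  invisible(cfg)
}

#' Read a YAML configuration file
#'
#' Unknown keys are rejected; missing keys take the [panelConfig()] defaults.
#'
#' @param path YAML file path.
#' @return a `pdm_config` list.
#' @export
readPanelConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(panelConfig, raw)
}

#' Hash of a resolved configuration
#'
#' MD5 over the deparsed, name-sorted configuration; used to stamp output
#' tables so every run is self-describing.
#'
#' @param cfg a `pdm_config` list.
#' @return character scalar.
#' @export
configHash <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 15), collapse = ","), ""), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}
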