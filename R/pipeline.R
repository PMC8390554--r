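#' Run the full synthetic-study pipeline
#'
#' Orchestrates every stage on a simulated panel: data generation (a primary
#' dataset plus a replication dataset sharing the same planted truth but
#' independent noise), preprocessing, per-cytosine differential fits,
#' the enrichment suite (direction, elements, TSS bins, pathways, genes),
#' rank aggregation across the two datasets, the age-effect suite, and
#' cross-dataset concordance.  Every output table is written as TSV stamped
#' with the config hash and seed, and a manifest of MD5 digests makes
#' determinism checkable: identical config + seed reproduce identical
#' digests.
#'
#' @param simCfg a [simConfig()] list describing the synthetic study.
#' @param config a [panelConfig()] list of analysis thresholds.
#' @param outdir output directory.
#' @param seed master seed; overrides `simCfg$seed` and `config$rng_seed`.
#' @return list with the in-memory stage results and `manifest`
#'   (`data.frame` of file digests), invisibly.
#' @export
runAll <- function(simCfg = simConfig(), config = panelConfig(),
                   outdir = tempfile("padlockDM_run"), seed = simCfg$seed) {
  t0 <- Sys.time()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  simCfg$seed <- seed
  config$rng_seed <- seed
  chash <- configHash(config)
  pdmLog("run-all: seed=%d outdir=%s", seed, outdir)
  pdmLog("config: %s", paste(names(config), unlist(lapply(config, paste,
         collapse = ",")), sep = "=", collapse = " "))

  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    pdmLog("stage %-12s %.1fs", name, as.numeric(Sys.time() - ts, units = "secs"))
    res
  }

  sim <- stage("simulate", simulatePanel(simCfg))
  repCfg <- simCfg
  repCfg$noise_seed <- streamSeed(seed, "replicates")
  simRep <- stage("simulate_rep", simulatePanel(repCfg))
  writeSimulation(sim, file.path(outdir, "input"))

  prep <- stage("preprocess", preprocessPanel(sim$counts, sim$annotation, config))
  prepRep <- stage("preprocess_rep",
                   preprocessPanel(simRep$counts, simRep$annotation, config))
  writeTsv(prep$report$stages, file.path(outdir, "qc_report.tsv"), chash, seed)

  fits <- stage("fit", runDifferential(prep$counts, config))
  fitsRep <- stage("fit_rep", runDifferential(prepRep$counts, config))
  writeTsv(as.data.frame(fits), file.path(outdir, "fits.tsv"), chash, seed)

  enr <- stage("enrich", {
    list(direction = directionalEnrichment(fits),
         elements = elementEnrichment(fits, sim$annotation),
         tss_bins = tssBinEnrichment(fits, sim$annotation, config$tss_bin_bp),
         pathways = pathwayEnrichment(fits, sim$annotation),
         genes = geneStats(fits, sim$annotation))
  })
  writeTsv(enr$direction, file.path(outdir, "enrich_direction.tsv"), chash, seed)
  writeTsv(enr$elements, file.path(outdir, "enrich_elements.tsv"), chash, seed)
  writeTsv(enr$tss_bins, file.path(outdir, "enrich_tss_bins.tsv"), chash, seed)
  if (!is.null(enr$pathways))
    writeTsv(enr$pathways, file.path(outdir, "enrich_pathways.tsv"), chash, seed)
  writeTsv(enr$genes, file.path(outdir, "gene_stats.tsv"), chash, seed)

  agg <- stage("aggregate", {
    genesRep <- geneStats(fitsRep, simRep$annotation)
    aggregateGeneRanks(list(primary = enr$genes, replication = genesRep))
  })
  writeTsv(agg, file.path(outdir, "rra_genes.tsv"), chash, seed)

  aging <- stage("aging", {
    agefit <- fitAgeModel(prep$counts, config)
    rc <- geneAgingRate(agefit, sim$annotation, "control", config$fdr_q)
    rp <- geneAgingRate(agefit, sim$annotation, "case", config$fdr_q)
    cmp <- compareGroupRates(rc, rp)
    corr <- agePdCorrelation(agefit[agefit$contrast == "age_control", ], fits)
    list(agefit = agefit, rates_control = rc, rates_case = rp,
         comparison = cmp, age_pd = corr)
  })
  writeTsv(aging$rates_control, file.path(outdir, "aging_rates_control.tsv"),
           chash, seed)
  writeTsv(aging$rates_case, file.path(outdir, "aging_rates_case.tsv"),
           chash, seed)

  conc <- stage("concord", {
    orA <- setNames(enr$genes$or_value, enr$genes$gene_id)
    gsRep <- geneStats(fitsRep, simRep$annotation)
    orB <- setNames(gsRep$or_value, gsRep$gene_id)
    list(kendall = kendallConcordance(orA, orB),
         exacerbation = exacerbationTest(fits, fitsRep),
         top_elements = topSitesElementConcordance(fits, fitsRep,
                                                   sim$annotation,
                                                   k = min(1000, nrow(fits))))
  })
  concord_df <- data.frame(statistic = c("kendall_tau", "kendall_p",
                                         "exacerbation_or", "exacerbation_p"),
                           value = c(conc$kendall$tau, conc$kendall$p,
                                     conc$exacerbation$or_value,
                                     conc$exacerbation$p))
  writeTsv(concord_df, file.path(outdir, "concordance.tsv"), chash, seed)

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  manifest <- data.frame(file = sub(paste0("^", outdir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  meta <- data.frame(file = c("_config_hash", "_seed"),
                     md5 = c(chash, as.character(seed)))
  writeTsv(rbind(meta, manifest), file.path(outdir, "manifest.tsv"))
  pdmLog("run-all complete in %.1fs",
         as.numeric(Sys.time() - t0, units = "secs"))
  invisible(list(sim = sim, preprocess = prep, fits = fits,
                 enrichment = enr, aggregation = agg, aging = aging,
                 concordance = conc, manifest = manifest, outdir = outdir))
}
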