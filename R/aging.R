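#' Per-cytosine age-effect models
#'
#' Fits the differential engine with diagnosis, age, and a diagnosis-age
#' interaction (plus the usual covariates and surrogates) and reports three
#' contrasts: `age_control` (the age coefficient), `age_case` (age +
#' interaction), and `age_interaction` (case slope minus control slope).
#' Slopes are in percentage points per year; BH adjustment is applied within
#' each contrast.
#'
#' @param counts preprocessed [MethylCountSet-class] with `group` and `age`.
#' @param config a [panelConfig()] list.
#' @param covariates additional design covariates (default auto-detected,
#'   see [buildDesign()]).
#' @param surrogates estimate surrogate variables (default `TRUE`).
#' @return `pdm_fit_table` with the three age contrasts.
#' @export
fitAgeModel <- function(counts, config = panelConfig(), covariates = NULL,
                        surrogates = TRUE) {
  sheet <- sampleSheet(counts)
  stopIfNot("age" %in% names(sheet) && length(unique(sheet$age)) > 1,
            "age must be present and non-constant")
  if (is.null(covariates)) {
    cand <- c("group", "age", "sex", "pmi", "batch")
    covariates <- cand[vapply(cand, function(v)
      v %in% names(sheet) && length(unique(sheet[[v]])) > 1, TRUE)]
  }
  stopIfNot(all(c("group", "age") %in% covariates),
            "age model needs both group and age")
  X0 <- buildDesign(sheet, covariates, interactions = "group:age")
  int_col <- grep(":age$|^age:", colnames(X0), value = TRUE)
  stopIfNot(length(int_col) == 1, "could not locate the group:age column")
  C <- matrix(0, ncol(X0), 3,
              dimnames = list(colnames(X0),
                              c("age_control", "age_case", "age_interaction")))
  C["age", ] <- c(1, 1, 0)
  C[int_col, ] <- c(0, 1, 1)
  runDifferential(counts, config, covariates = covariates,
                  interactions = "group:age", contrasts = C,
                  report_contrasts = colnames(C), surrogates = surrogates)
}

#' Per-gene epigenetic aging rate
#'
#' The gene's aging rate is the weighted mean of its cytosines' age slopes,
#' weights `-log10` of the aging p value (most significant cytosines weigh
#' most).  The rate is forced to zero — and flagged — for genes without a
#' single cytosine significantly affected by age (FDR `q < fdrQ`).
#'
#' @param agefit `pdm_fit_table` from [fitAgeModel()].
#' @param annotation a [PanelAnnotation-class].
#' @param group `"control"` or `"case"` — which age contrast to summarize.
#' @param fdrQ zeroing threshold (study value 0.05).
#' @param weightBase base of the log p-value weights.
#' @return `data.frame`: `gene_id`, `rate` (points/year), `zeroed`,
#'   `n_sites`, `n_sig`.
#' @export
geneAgingRate <- function(agefit, annotation, group = c("control", "case"),
                          fdrQ = 0.05, weightBase = 10) {
  group <- match.arg(group)
  fits <- agefit[agefit$contrast == paste0("age_", group), ]
  stopIfNot(nrow(fits) > 0, "no '%s' age contrast in fit table", group)
  fits <- fits[!is.na(fits$p), ]
  gene <- assignGenes(fits, annotation)
  out <- list()
  for (gid in sort(unique(gene[!is.na(gene)]))) {
    sel <- which(gene %in% gid)
    w <- -log(fits$p[sel], base = weightBase)
    if (any(!is.finite(w)))
      w[!is.finite(w)] <- if (any(is.finite(w))) max(w[is.finite(w)]) + 1 else 1
    rate <- if (sum(w) > 0) sum(w * fits$pct_change[sel]) / sum(w)
            else mean(fits$pct_change[sel])
    n_sig <- sum(fits$q[sel] < fdrQ, na.rm = TRUE)
    zeroed <- n_sig == 0
    out[[gid]] <- data.frame(gene_id = gid,
                             rate = if (zeroed) 0 else rate,
                             zeroed = zeroed, n_sites = length(sel),
                             n_sig = n_sig, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlation of age and disease effect magnitudes
#'
#' Restricts to loci nominally significant (`p < nominalP`) in both tables
#' and computes the Pearson correlation between absolute age slopes and
#' absolute disease effects.
#'
#' @param agefit single-contrast age fit table (e.g. the `age_control` rows).
#' @param pdfit single-contrast disease fit table.
#' @param nominalP nominal threshold (default 0.05).
#' @return list with `r`, `p`, `n`, or `NULL` (with a log message) when
#'   fewer than 3 loci qualify.
#' @export
agePdCorrelation <- function(agefit, pdfit, nominalP = 0.05) {
  agefit <- oneContrast(agefit); pdfit <- oneContrast(pdfit)
  a <- agefit[!is.na(agefit$p) & agefit$p < nominalP, ]
  b <- pdfit[!is.na(pdfit$p) & pdfit$p < nominalP, ]
  shared <- intersect(a$key, b$key)
  if (length(shared) < 3) {
    pdmLog("only %d loci nominally significant in both; no correlation",
           length(shared))
    return(NULL)
  }
  x <- abs(a$pct_change[match(shared, a$key)])
  y <- abs(b$pct_change[match(shared, b$key)])
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Compare aging-rate tables between groups
#'
#' Three statistics over a shared gene universe: (1) overlap enrichment of
#' non-zeroed genes (two-sided Fisher); (2) direction agreement among
#' jointly non-zeroed genes (Fisher on the sign cross-table); (3) paired t
#' test on absolute rates over jointly non-zeroed genes (are case genes
#' aging faster in magnitude?).
#'
#' @param rates_control,rates_case [geneAgingRate()] tables over the same
#'   genes.
#' @return list with `overlap`, `direction_agreement` (enrichment rows) and
#'   `paired_t` (`statistic`, `p`, `n`, `mean_abs_control`,
#'   `mean_abs_case`); tests are `NULL` (and logged) when fewer than 2
#'   jointly non-zeroed genes exist.
#' @export
compareGroupRates <- function(rates_control, rates_case) {
  universe <- union(rates_control$gene_id, rates_case$gene_id)
  nzC <- rates_control$gene_id[!rates_control$zeroed]
  nzP <- rates_case$gene_id[!rates_case$zeroed]
  joint <- intersect(nzC, nzP)
  overlap <- if (length(universe))
    genesetOverlap(nzC, nzP, universe) else NULL
  if (length(joint) < 2) {
    pdmLog("fewer than 2 jointly non-zeroed genes; comparisons skipped")
    return(list(overlap = overlap, direction_agreement = NULL, paired_t = NULL))
  }
  rc <- rates_control$rate[match(joint, rates_control$gene_id)]
  rp <- rates_case$rate[match(joint, rates_case$gene_id)]
  dir_agree <- fisherFromFlags(rp > 0, rc > 0, label = "direction_agreement")
  d <- abs(rp) - abs(rc)
  if (sd(d) == 0) {
    paired <- list(statistic = 0, p = if (all(d == 0)) 1 else 0,
                   n = length(joint), mean_abs_control = mean(abs(rc)),
                   mean_abs_case = mean(abs(rp)))
  } else {
    tt <- t.test(abs(rp), abs(rc), paired = TRUE)
    paired <- list(statistic = unname(tt$statistic), p = tt$p.value,
                   n = length(joint), mean_abs_control = mean(abs(rc)),
                   mean_abs_case = mean(abs(rp)))
  }
  list(overlap = overlap, direction_agreement = dir_agree, paired_t = paired)
}
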