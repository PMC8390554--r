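## QC report helpers -------------------------------------------------------

newQCReport <- function() {
  structure(list(
    stages = data.frame(stage = character(), unit = character(),
                        before = integer(), removed = integer(),
                        after = integer(), stringsAsFactors = FALSE),
    removed_sites = data.frame(key = character(), reason = character(),
                               stringsAsFactors = FALSE),
    excluded_samples = data.frame(sample_id = character(), reason = character(),
                                  stringsAsFactors = FALSE)),
    class = "pdm_qcreport")
}

addStage <- function(report, stage, unit, before, after) {
  report$stages <- rbind(report$stages,
                         data.frame(stage = stage, unit = unit,
                                    before = before, removed = before - after,
                                    after = after, stringsAsFactors = FALSE))
  report
}

addRemovedSites <- function(report, keys, reason) {
  if (length(keys))
    report$removed_sites <- rbind(report$removed_sites,
                                  data.frame(key = keys, reason = reason,
                                             stringsAsFactors = FALSE))
  report
}

addExcludedSamples <- function(report, ids, reason) {
  if (length(ids))
    report$excluded_samples <- rbind(report$excluded_samples,
                                     data.frame(sample_id = ids, reason = reason,
                                                stringsAsFactors = FALSE))
  report
}

#' @export
print.pdm_qcreport <- function(x, ...) {
  cat("padlockDM QC report\n")
  print(x$stages, row.names = FALSE)
  if (nrow(x$excluded_samples)) {
    cat("excluded samples:\n")
    print(x$excluded_samples, row.names = FALSE)
  }
  invisible(x)
}

## Operations ---------------------------------------------------------------

#' Minimum-coverage filter
#'
#' Cells with read depth `M + U` below `minCoverage` become missing; retained
#' cells are unchanged.  The study threshold is 30x.
#'
#' @param counts a [MethylCountSet-class].
#' @param minCoverage integer `>= 1`.
#' @return filtered [MethylCountSet-class].
#' @export
coverageFilter <- function(counts, minCoverage = 30) {
  stopIfNot(minCoverage >= 1, "minCoverage must be >= 1")
  M <- methReads(counts); U <- unmethReads(counts)
  low <- !is.na(M) & (M + U < minCoverage)
  M[low] <- NA_integer_; U[low] <- NA_integer_
  MethylCountSet(M, U, cytosineKeys(counts), sampleSheet(counts))
}

#' Technical-replicate QC and merging
#'
#' Replicate pairs whose Pearson correlation of beta values is at or below
#' `minR` trigger an exclusion: the member with the lower median coverage is
#' dropped (configurable policy; both members are recorded in the report).
#' Surviving members of each replicate group are collapsed into one column by
#' averaging `M` and `U` (rounded half-up), named by the group id.
#'
#' @param counts a [MethylCountSet-class] whose sample sheet has a
#'   `replicate_group` column (`NA` for singleton samples).
#' @param minR correlation floor (study value 0.9; exclusion at `r <= minR`).
#' @param report optional existing QC report to append to.
#' @return list with `counts` (merged) and `report`.
#' @export
mergeReplicates <- function(counts, minR = 0.9, report = newQCReport()) {
  sheet <- sampleSheet(counts)
  if (!"replicate_group" %in% names(sheet) || all(is.na(sheet$replicate_group)))
    return(list(counts = counts, report = addStage(report, "replicate_merge",
                                                   "samples", ncol(counts),
                                                   ncol(counts))))
  before <- ncol(counts)
  B <- betaValues(counts)
  M <- methReads(counts); U <- unmethReads(counts)
  grp <- sheet$replicate_group
  drop_ids <- character()
  keepM <- list(); keepU <- list(); keepRows <- list()
  singles <- which(is.na(grp))
  for (i in singles) {
    keepM[[sheet$sample_id[i]]] <- M[, i]
    keepU[[sheet$sample_id[i]]] <- U[, i]
    keepRows[[sheet$sample_id[i]]] <- sheet[i, ]
  }
  for (g in unique(grp[!is.na(grp)])) {
    idx <- which(grp %in% g)
    if (length(idx) == 1) {
      warning(sprintf("replicate group '%s' has a single member; passed through", g))
      id <- sheet$sample_id[idx]
      keepM[[id]] <- M[, idx]; keepU[[id]] <- U[, idx]
      keepRows[[id]] <- sheet[idx, ]
      next
    }
    ## flag low-correlation pairs; drop the lower-median-coverage member
    excl <- integer()
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
      r <- suppressWarnings(cor(B[, idx[a]], B[, idx[b]],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r <= minR) {
        covmed <- vapply(idx[c(a, b)], function(j)
          median(M[, j] + U[, j], na.rm = TRUE), 0)
        worse <- idx[c(a, b)][which.min(covmed)]
        excl <- union(excl, worse)
        report <- addExcludedSamples(report, sheet$sample_id[idx[c(a, b)]],
                                     sprintf("replicate r = %.3f <= %.2f (excluded: %s)",
                                             r, minR, sheet$sample_id[worse]))
      }
    }
    drop_ids <- c(drop_ids, sheet$sample_id[excl])
    idx <- setdiff(idx, excl)
    if (!length(idx)) next
    mm <- roundHalfUp(rowMeans(M[, idx, drop = FALSE], na.rm = TRUE))
    uu <- roundHalfUp(rowMeans(U[, idx, drop = FALSE], na.rm = TRUE))
    allna <- rowSums(!is.na(M[, idx, drop = FALSE])) == 0
    mm[allna] <- NA_integer_; uu[allna] <- NA_integer_
    row <- sheet[idx[1], ]
    row$sample_id <- g
    row$replicate_group <- NA_character_
    keepM[[g]] <- as.integer(mm); keepU[[g]] <- as.integer(uu)
    keepRows[[g]] <- row
  }
  newSheet <- do.call(rbind, keepRows)
  rownames(newSheet) <- NULL
  Mn <- do.call(cbind, keepM); Un <- do.call(cbind, keepU)
  colnames(Mn) <- colnames(Un) <- newSheet$sample_id
  out <- MethylCountSet(Mn, Un, cytosineKeys(counts), newSheet)
  report <- addStage(report, "replicate_merge", "samples", before, ncol(out))
  list(counts = out, report = report)
}

#' Site-level filters
#'
#' Applies, in order: (1) call-rate filter — sites observed in fewer than
#' `minCallRate` of samples are removed; (2) all-zero filter — sites where
#' every observed call is 0% methylation; (3) SNP mask — sites whose position
#' falls in the mask; (4) stable-site filter — sites where the fraction of
#' samples at exactly 0%, exactly 100%, or missing is `>=` `stableFraction`.
#'
#' @param counts a [MethylCountSet-class].
#' @param annotation optional [PanelAnnotation-class] supplying the SNP mask.
#' @param minCallRate call-rate threshold (study value 0.7).
#' @param stableFraction stable-site threshold (study value 0.5, inclusive).
#' @param stages subset of `c("callrate", "allzero", "snp", "stable")` to run.
#' @param report optional QC report to append to.
#' @return list with `counts` and `report`.
#' @export
siteFilters <- function(counts, annotation = NULL, minCallRate = 0.7,
                        stableFraction = 0.5,
                        stages = c("callrate", "allzero", "snp", "stable"),
                        report = newQCReport()) {
  dropStage <- function(counts, bad, stage) {
    report <<- addStage(report, stage, "sites", nrow(counts),
                        nrow(counts) - sum(bad))
    report <<- addRemovedSites(report, rownames(counts)[bad], stage)
    counts[!bad, ]
  }
  if ("callrate" %in% stages) {
    rate <- rowMeans(!is.na(methReads(counts)))
    counts <- dropStage(counts, rate < minCallRate, "callrate")
  }
  if ("allzero" %in% stages) {
    B <- betaValues(counts)
    obs <- rowSums(!is.na(B))
    allz <- obs > 0 & rowSums(B == 0, na.rm = TRUE) == obs
    counts <- dropStage(counts, allz, "allzero")
  }
  if ("snp" %in% stages && !is.null(annotation) &&
      length(panelSnpMask(annotation))) {
    hit <- overlapsAny(rowRanges(counts), panelSnpMask(annotation),
                       ignore.strand = TRUE)
    counts <- dropStage(counts, hit, "snp_mask")
  }
  if ("stable" %in% stages) {
    B <- betaValues(counts)
    frac <- rowMeans(is.na(B) | B == 0 | B == 1)
    counts <- dropStage(counts, frac >= stableFraction, "stable")
  }
  stopIfNot(nrow(counts) > 0, "no sites remain after site filters")
  as(counts, "MethylCountSet")
  list(counts = as(counts, "MethylCountSet"), report = report)
}

#' Quantile-normalize count matrices
#'
#' `M` and `U` are quantile-normalized independently across samples (each
#' column's values are replaced by the mean of the column-sorted values at
#' the same rank; ties receive the average of their reference quantiles;
#' missing cells are interpolated on the quantile scale and restored
#' missing), then rounded half-up back to integers.
#'
#' @param counts a [MethylCountSet-class].
#' @return normalized [MethylCountSet-class].
#' @export
quantileNormalizeCounts <- function(counts) {
  M <- methReads(counts); U <- unmethReads(counts)
  qn <- function(X) {
    miss <- is.na(X)
    Y <- roundHalfUp(limma::normalizeQuantiles(X, ties = TRUE))
    Y[miss] <- NA
    Y[Y < 0] <- 0L
    storage.mode(Y) <- "integer"
    Y
  }
  MethylCountSet(qn(M), qn(U), cytosineKeys(counts), sampleSheet(counts))
}

#' PCA sample-outlier detection
#'
#' PCA of beta values (sites mean-imputed solely for this step); samples
#' whose projection on PC1 or PC2 deviates from that component's mean by more
#' than `outlierSD` standard deviations of its scores are flagged.  Single
#' pass, no re-iteration.
#'
#' @param counts a [MethylCountSet-class] (`>= 4` samples).
#' @param outlierSD threshold in score standard deviations (study value 3).
#' @param report optional QC report to append to.
#' @return list with `excluded` (sample ids), `scores` (samples x 2), and
#'   `report`.
#' @export
pcaOutliers <- function(counts, outlierSD = 3, report = newQCReport()) {
  stopIfNot(ncol(counts) >= 4, "PCA outlier detection needs >= 4 samples")
  B <- betaValues(counts)
  obs <- rowSums(!is.na(B))
  stopIfNot(sum(obs == ncol(B)) >= 3 || sum(obs > 0) >= 3,
            "fewer than 3 informative sites for PCA")
  keep <- obs > 0
  B <- B[keep, , drop = FALSE]
  mu <- rowMeans(B, na.rm = TRUE)
  idx <- which(is.na(B), arr.ind = TRUE)
  if (nrow(idx)) B[idx] <- mu[idx[, 1]]
  B <- B[apply(B, 1, function(r) var(r) > 0), , drop = FALSE]
  stopIfNot(nrow(B) >= 3, "fewer than 3 variable sites for PCA")
  pc <- prcomp(t(B), center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1:2, drop = FALSE]
  dev <- sweep(sc, 2, colMeans(sc))
  sds <- apply(sc, 2, sd)
  flag <- abs(dev[, 1]) > outlierSD * sds[1] | abs(dev[, 2]) > outlierSD * sds[2]
  excluded <- colnames(counts)[flag]
  report <- addExcludedSamples(report, excluded,
                               sprintf("PC score > %g SD", outlierSD))
  report <- addStage(report, "pca_outliers", "samples", ncol(counts),
                     ncol(counts) - length(excluded))
  list(excluded = excluded, scores = sc, report = report)
}

#' Full preprocessing chain
#'
#' Applies, in order: coverage filter, replicate QC/merge, call-rate /
#' all-zero / SNP-mask filters, optional quantile normalization, stable-site
#' filter, and PCA outlier removal.  The stable-site pass runs after
#' normalization, mirroring the two-stage site filtering of the published
#' pipeline; stage counts in the report telescope.
#'
#' @param counts a [MethylCountSet-class] with sample sheet attached.
#' @param annotation optional [PanelAnnotation-class] (SNP mask).
#' @param config a [panelConfig()] list.
#' @return list with `counts` (filtered), `beta` (beta-value matrix), and
#'   `report`.
#' @export
preprocessPanel <- function(counts, annotation = NULL, config = panelConfig()) {
  report <- newQCReport()
  ncells_before <- sum(!is.na(methReads(counts)))
  filtered <- coverageFilter(counts, config$min_coverage)
  report <- addStage(report, "coverage", "cells", ncells_before,
                     sum(!is.na(methReads(filtered))))
  mr <- mergeReplicates(filtered, config$replicate_min_r, report)
  filtered <- mr$counts; report <- mr$report
  sf <- siteFilters(filtered, annotation, config$min_call_rate,
                    config$stable_fraction,
                    stages = c("callrate", "allzero", "snp"), report = report)
  filtered <- sf$counts; report <- sf$report
  if (isTRUE(config$quantile_normalize))
    filtered <- quantileNormalizeCounts(filtered)
  sf <- siteFilters(filtered, annotation, stages = "stable",
                    stableFraction = config$stable_fraction, report = report)
  filtered <- sf$counts; report <- sf$report
  po <- pcaOutliers(filtered, config$outlier_sd, report)
  report <- po$report
  if (length(po$excluded))
    filtered <- as(filtered[, !colnames(filtered) %in% po$excluded],
                   "MethylCountSet")
  list(counts = filtered, beta = betaValues(filtered), report = report)
}
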