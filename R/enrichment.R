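## fit-table helpers --------------------------------------------------------

oneContrast <- function(fits) {
  if ("contrast" %in% names(fits) && length(unique(fits$contrast)) > 1)
    stop("fit table contains multiple contrasts; subset to one first",
         call. = FALSE)
  fits
}

siteRanges <- function(fits) {
  GRanges(fits$chrom, IRanges(fits$pos, width = 1))
}

#' Fisher odds-ratio test of a 2x2 table
#'
#' Cells are (a, b) foreground in/out and (c, d) background in/out.  The
#' reported odds ratio is the sample OR \eqn{ad / bc} (infinite when
#' `b * c == 0` with `a * d > 0`); the p value is the exact hypergeometric
#' test (two-sided by the point-probability rule, or the upper tail for
#' `alternative = "greater"`); the 95% CI is the Woolf log-OR interval with
#' the Haldane 0.5 correction applied when any cell is zero.
#'
#' @param a,b,c,d non-negative integer cell counts (total > 0).
#' @param alternative `"two.sided"` or `"greater"`.
#' @param label optional analysis label carried into the result.
#' @return one-row `data.frame`: `label`, `a`..`d`, `or_value`, `p`,
#'   `ci_low`, `ci_high`, `n_fg`, `n_bg`.
#' @examples
#' fisherOddsRatio(10, 90, 10, 90)
#' @export
fisherOddsRatio <- function(a, b, c, d, alternative = c("two.sided", "greater"),
                            label = NA_character_) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  stopIfNot(all(cells >= 0), "cell counts must be non-negative")
  stopIfNot(sum(cells) > 0, "all-zero 2x2 table")
  or_value <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  tab <- matrix(as.numeric(cells), 2, 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = alternative)$p.value
  h <- cells + if (any(cells == 0)) 0.5 else 0
  lor <- log((h[1] * h[4]) / (h[2] * h[3]))
  se <- sqrt(sum(1 / h))
  data.frame(label = label, a = a, b = b, c = c, d = d,
             or_value = or_value, p = p,
             ci_low = exp(lor - qnorm(0.975) * se),
             ci_high = exp(lor + qnorm(0.975) * se),
             n_fg = a + b, n_bg = c + d, stringsAsFactors = FALSE)
}

fisherFromFlags <- function(fg, inside, alternative = "two.sided", label = NA) {
  fisherOddsRatio(sum(fg & inside), sum(fg & !inside),
                  sum(!fg & inside), sum(!fg & !inside),
                  alternative = alternative, label = label)
}

#' Hyper- vs hypomethylation bias of significant cytosines
#'
#' Tests whether hypermethylated loci are over-represented among
#' significantly differentially methylated cytosines relative to the rest of
#' the interrogated loci: 2x2 of significant/not x hyper/hypo, two-sided
#' Fisher test.
#'
#' @param fits a single-contrast fit table from [runDifferential()].
#' @return one-row enrichment `data.frame`; when no site is significant the
#'   result has `n_fg = 0` and `p = 1`.
#' @export
directionalEnrichment <- function(fits) {
  fits <- oneContrast(fits)
  fits <- fits[!is.na(fits$q) & fits$direction != 0, ]
  sig <- fits$significant
  if (!any(sig)) {
    out <- data.frame(label = "hyper_vs_hypo", a = 0, b = 0,
                      c = sum(fits$direction > 0), d = sum(fits$direction < 0),
                      or_value = NA_real_, p = 1, ci_low = NA_real_,
                      ci_high = NA_real_, n_fg = 0, n_bg = nrow(fits))
    return(out)
  }
  fisherFromFlags(sig, fits$direction > 0, label = "hyper_vs_hypo")
}

#' Assign cytosines to panel genes
#'
#' Each cytosine is assigned to the nearest panel-gene TSS among genes whose
#' probed window contains the site; ties are broken lexicographically by
#' `gene_id`.  Sites in no window get `NA`.
#'
#' @param fits fit table (or any `data.frame` with `chrom` and `pos`).
#' @param annotation a [PanelAnnotation-class].
#' @return character vector of gene ids, same length as `nrow(fits)`.
#' @export
assignGenes <- function(fits, annotation) {
  g <- panelGenes(annotation)
  o <- order(g$gene_id)
  g <- g[o, ]
  win <- GRanges(g$chrom, IRanges(pmax(g$tss - g$window_bp, 1L),
                                  g$tss + g$window_bp))
  sites <- siteRanges(fits)
  hits <- findOverlaps(sites, win, ignore.strand = TRUE)
  d <- abs(fits$pos[S4Vectors::queryHits(hits)] -
             g$tss[S4Vectors::subjectHits(hits)])
  ## order by distance then gene_id (already sorted) so first hit wins
  ord <- order(S4Vectors::queryHits(hits), d, S4Vectors::subjectHits(hits))
  qh <- S4Vectors::queryHits(hits)[ord]
  sh <- S4Vectors::subjectHits(hits)[ord]
  first <- !duplicated(qh)
  res <- rep(NA_character_, nrow(fits))
  res[qh[first]] <- g$gene_id[sh[first]]
  res
}

#' Genomic-element enrichment of differential methylation
#'
#' For each element class, tests whether significant cytosines (optionally
#' restricted to the hyper- or hypomethylated subset) fall inside the class's
#' intervals more often than the remaining interrogated sites do.
#'
#' @param fits single-contrast fit table.
#' @param annotation a [PanelAnnotation-class] with element intervals.
#' @param subset `"all"`, `"hyper"`, or `"hypo"` — restriction of the
#'   significant (foreground) set by direction.
#' @return `data.frame`, one row per element class; classes with no
#'   overlapping panel site are reported with counts and `NA` statistics.
#' @export
elementEnrichment <- function(fits, annotation, subset = c("all", "hyper", "hypo")) {
  subset <- match.arg(subset)
  fits <- oneContrast(fits)
  fits <- fits[!is.na(fits$q), ]
  sig <- fits$significant
  if (subset == "hyper") sig <- sig & fits$direction > 0
  if (subset == "hypo") sig <- sig & fits$direction < 0
  sites <- siteRanges(fits)
  out <- lapply(names(panelElements(annotation)), function(cls) {
    inside <- overlapsAny(sites, panelElements(annotation)[[cls]],
                          ignore.strand = TRUE)
    if (!any(inside))
      return(data.frame(label = cls, a = 0, b = sum(sig), c = 0,
                        d = sum(!sig), or_value = NA_real_, p = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_fg = sum(sig), n_bg = sum(!sig)))
    fisherFromFlags(sig, inside, label = cls)
  })
  res <- do.call(rbind, out)
  res$subset <- subset
  res
}

#' TSS-distance bin enrichment
#'
#' Every cytosine is assigned a `binBp`-wide bin (default 20 kb, half-open:
#' a site at exactly 20,000 bp falls in bin 2) from the absolute distance to
#' the nearest panel-gene TSS.  Within each gene stratum, the odds of
#' significant cytosines inside a bin are compared against those outside the
#' bin in the same stratum.
#'
#' @param fits single-contrast fit table.
#' @param annotation a [PanelAnnotation-class].
#' @param binBp bin width in bp.
#' @param strata named list of gene-id vectors partitioning the panel (a
#'   site's stratum is its nearest gene's stratum); default one stratum
#'   `"all"`.
#' @param maxBins report at most this many bins (counted from the TSS).
#' @return `data.frame`, one row per (stratum, bin); degenerate strata (all
#'   sites in one bin) are reported without a p value.
#' @export
tssBinEnrichment <- function(fits, annotation, binBp = 20000, strata = NULL,
                             maxBins = 15) {
  fits <- oneContrast(fits)
  fits <- fits[!is.na(fits$q), ]
  g <- panelGenes(annotation)
  ## nearest TSS over all panel genes (unsigned distance)
  sites <- siteRanges(fits)
  tssGR <- GRanges(g$chrom, IRanges(g$tss, width = 1))
  nearestIdx <- GenomicRanges::nearest(sites, tssGR, ignore.strand = TRUE)
  dist <- abs(fits$pos - g$tss[nearestIdx])
  bin <- floor(dist / binBp) + 1L
  gene <- g$gene_id[nearestIdx]
  if (is.null(strata)) strata <- list(all = g$gene_id)
  out <- list()
  for (st in names(strata)) {
    insel <- gene %in% strata[[st]]
    sig <- fits$significant[insel]
    bins <- bin[insel]
    for (bb in sort(unique(pmin(bins, maxBins)))) {
      inb <- bins == bb
      r <- if (all(inb) || !any(inb)) data.frame(
        label = sprintf("%s:bin%d", st, bb), a = sum(sig & inb),
        b = sum(sig & !inb), c = sum(!sig & inb), d = sum(!sig & !inb),
        or_value = NA_real_, p = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, n_fg = sum(sig), n_bg = sum(!sig))
      else fisherFromFlags(sig, inb, label = sprintf("%s:bin%d", st, bb))
      r$n_in <- sum(inb)
      out[[length(out) + 1]] <- r
    }
  }
  res <- do.call(rbind, out)
  res$stratum <- sub(":bin\\d+$", "", res$label)
  res$bin <- as.integer(sub("^.*:bin", "", res$label))
  res
}

#' Pathway enrichment of differential methylation
#'
#' For each pathway, compares the odds of significant cytosines (optionally
#' restricted by direction) at the pathway's genes against significant
#' cytosines at all other panel genes.
#'
#' @param fits single-contrast fit table.
#' @param annotation a [PanelAnnotation-class] with pathway memberships.
#' @param subset `"all"`, `"hyper"`, or `"hypo"`.
#' @return `data.frame`, one row per non-empty pathway.
#' @export
pathwayEnrichment <- function(fits, annotation, subset = c("all", "hyper", "hypo")) {
  subset <- match.arg(subset)
  fits <- oneContrast(fits)
  fits <- fits[!is.na(fits$q), ]
  gene <- assignGenes(fits, annotation)
  keep <- !is.na(gene)
  fits <- fits[keep, ]; gene <- gene[keep]
  sig <- fits$significant
  if (subset == "hyper") sig <- sig & fits$direction > 0
  if (subset == "hypo") sig <- sig & fits$direction < 0
  g <- panelGenes(annotation)
  pw_all <- sort(unique(unlist(g$pathways)))
  out <- list()
  for (pw in pw_all) {
    pw_genes <- g$gene_id[vapply(g$pathways, function(p) pw %in% p, TRUE)]
    inpw <- gene %in% pw_genes
    if (!any(inpw)) { pdmLog("pathway '%s' has no panel sites; skipped", pw); next }
    out[[pw]] <- fisherFromFlags(sig, inpw, label = pw)
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) { res$subset <- subset; rownames(res) <- NULL }
  res
}

#' Per-gene enrichment statistics
#'
#' For each panel gene: a one-sided (greater) Fisher test of the density of
#' significant cytosines within the gene versus all other interrogated
#' sites; the direction call (majority sign of the gene's significant
#' cytosines, ties resolved by the sign of the weighted mean fold change
#' over all the gene's cytosines, weights `-log10 p`); and the weighted mean
#' percentage-point change itself.
#'
#' @param fits single-contrast fit table.
#' @param annotation a [PanelAnnotation-class].
#' @param weightBase base of the `-log` p-value weights (default 10).
#' @return `data.frame` (one row per gene with `>= 1` assigned site):
#'   `gene_id`, `sig_in`, `nonsig_in`, `sig_out`, `nonsig_out`, `or_value`,
#'   `p_one_sided`, `direction`, `wmfc`, `n_sig`.
#' @export
geneStats <- function(fits, annotation, weightBase = 10) {
  fits <- oneContrast(fits)
  fits <- fits[!is.na(fits$q), ]
  gene <- assignGenes(fits, annotation)
  total_sig <- sum(fits$significant)
  total_nonsig <- sum(!fits$significant)
  out <- list()
  for (gid in sort(unique(gene[!is.na(gene)]))) {
    sel <- which(gene %in% gid)
    sig_in <- sum(fits$significant[sel])
    nonsig_in <- length(sel) - sig_in
    sig_out <- total_sig - sig_in
    nonsig_out <- total_nonsig - nonsig_in
    fr <- fisherOddsRatio(sig_in, nonsig_in, sig_out, nonsig_out,
                          alternative = "greater", label = gid)
    w <- -log(fits$p[sel], base = weightBase)
    if (any(!is.finite(w)))
      w[!is.finite(w)] <- if (any(is.finite(w))) max(w[is.finite(w)]) + 1 else 1
    wmfc <- if (sum(w) > 0) sum(w * fits$pct_change[sel]) / sum(w)
            else mean(fits$pct_change[sel])
    dirs <- fits$direction[sel][fits$significant[sel]]
    direction <- if (length(dirs) && sum(dirs > 0) != sum(dirs < 0))
      sign(sum(dirs > 0) - sum(dirs < 0)) else sign(wmfc)
    out[[gid]] <- data.frame(gene_id = gid, sig_in = sig_in,
                             nonsig_in = nonsig_in, sig_out = sig_out,
                             nonsig_out = nonsig_out, or_value = fr$or_value,
                             p_one_sided = fr$p, direction = direction,
                             wmfc = wmfc, n_sig = sig_in,
                             stringsAsFactors = FALSE)
  }
  missing <- setdiff(panelGenes(annotation)$gene_id, names(out))
  if (length(missing))
    pdmLog("%d gene(s) with no assigned panel sites omitted", length(missing))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap enrichment of two gene sets
#'
#' Two-sided Fisher test of membership in set A versus membership in set B
#' over a common gene universe.
#'
#' @param setA,setB character vectors (subsets of `universe`).
#' @param universe character vector of all genes considered.
#' @return one-row enrichment `data.frame`.
#' @export
genesetOverlap <- function(setA, setB, universe) {
  stopIfNot(length(universe) > 0, "empty gene universe")
  stopIfNot(all(setA %in% universe) && all(setB %in% universe),
            "sets must be subsets of the universe")
  inA <- universe %in% setA
  inB <- universe %in% setB
  fisherFromFlags(inA, inB, label = "set_overlap")
}

#' Cross-dataset concordance of top sites within genomic elements
#'
#' Takes the `k` most significant cytosines of each dataset and, per element
#' class, tests whether element instances hit by top sites in dataset A tend
#' to be the same instances hit in dataset B (2x2 of instance hit-in-A x
#' hit-in-B, two-sided Fisher).  When the two datasets carry their own
#' element annotations (e.g. tissue-specific enhancers), instances of the
#' same class are matched across annotations by overlap within `maxgap` bp
#' (study rule: 1 kb).
#'
#' @param fitsA,fitsB single-contrast fit tables.
#' @param annotation a [PanelAnnotation-class] for dataset A (and for B when
#'   `annotationB` is `NULL`).
#' @param k number of top sites per dataset (clamped with a warning when
#'   fewer sites are available).
#' @param annotationB optional [PanelAnnotation-class] for dataset B.
#' @param maxgap matching distance for cross-annotation instances.
#' @return `data.frame`, one row per element class.
#' @export
topSitesElementConcordance <- function(fitsA, fitsB, annotation, k = 5000,
                                       annotationB = NULL, maxgap = 1000) {
  fitsA <- oneContrast(fitsA); fitsB <- oneContrast(fitsB)
  kA <- min(k, nrow(fitsA)); kB <- min(k, nrow(fitsB))
  if (kA < k || kB < k)
    warning(sprintf("k clamped to %d/%d available sites", kA, kB))
  topA <- siteRanges(fitsA[order(fitsA$p), ][seq_len(kA), ])
  topB <- siteRanges(fitsB[order(fitsB$p), ][seq_len(kB), ])
  elA <- panelElements(annotation)
  elB <- if (is.null(annotationB)) elA else panelElements(annotationB)
  out <- list()
  for (cls in intersect(names(elA), names(elB))) {
    ia <- elA[[cls]]; ib <- elB[[cls]]
    if (is.null(annotationB)) {
      hitA <- overlapsAny(ia, topA, ignore.strand = TRUE)
      hitB <- overlapsAny(ia, topB, ignore.strand = TRUE)
    } else {
      mt <- findOverlaps(ia, ib, maxgap = maxgap, ignore.strand = TRUE)
      qa <- S4Vectors::queryHits(mt); qb <- S4Vectors::subjectHits(mt)
      pairA <- overlapsAny(ia[qa], topA, ignore.strand = TRUE)
      pairB <- overlapsAny(ib[qb], topB, ignore.strand = TRUE)
      soloA <- setdiff(seq_along(ia), qa)
      soloB <- setdiff(seq_along(ib), qb)
      hitA <- c(pairA, overlapsAny(ia[soloA], topA, ignore.strand = TRUE),
                rep(FALSE, length(soloB)))
      hitB <- c(pairB, rep(FALSE, length(soloA)),
                overlapsAny(ib[soloB], topB, ignore.strand = TRUE))
    }
    if (!length(hitA)) next
    if (all(hitA & hitB)) {
      out[[cls]] <- data.frame(label = cls, a = sum(hitA), b = 0, c = 0, d = 0,
                               or_value = Inf, p = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_, n_fg = sum(hitA), n_bg = 0)
      next
    }
    out[[cls]] <- fisherFromFlags(hitA, hitB, label = cls)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
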