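## all orderings of 1..n (n <= 8 in practice)
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                         drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

## tie-corrected Kendall tau-b
tauB <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(NA_real_)
  (C - D) / den
}

#' Kendall concordance of per-gene statistics across datasets
#'
#' Tie-corrected Kendall tau-b on paired per-gene values (odds ratios or any
#' monotone statistic — the coefficient makes no distributional assumption).
#' The two-sided p value is exact (full permutation enumeration) for
#' `n <= 8` pairs and a tie-corrected normal approximation otherwise.
#'
#' @param statsA,statsB named numeric vectors (gene -> statistic).  With a
#'   homolog `map`, names of `statsA`/`statsB` are the A/B-side gene ids.
#' @param map optional homolog map `data.frame` with columns `gene_a`,
#'   `gene_b` (reduced to one-to-one with [applyHomologMap()] rules).
#' @return list with `tau`, `p`, `n`; `tau` is `NA` (undefined) when either
#'   vector is constant.
#' @export
kendallConcordance <- function(statsA, statsB, map = NULL) {
  if (!is.null(map)) {
    map <- reduceHomologMap(map, statsA, statsB)
    x <- statsA[map$gene_a]; y <- statsB[map$gene_b]
  } else {
    shared <- intersect(names(statsA), names(statsB))
    x <- statsA[shared]; y <- statsB[shared]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopIfNot(n >= 3, "need at least 3 mapped gene pairs")
  tau <- tauB(x, y)
  if (is.na(tau)) {
    pdmLog("constant input vector; Kendall tau undefined")
    return(list(tau = NA_real_, p = NA_real_, n = n))
  }
  if (n <= 8) {
    perms <- allPermutations(n)
    taus <- apply(perms, 1, function(pp) tauB(x, y[pp]))
    p <- mean(abs(taus) >= abs(tau) - 1e-12, na.rm = TRUE)
  } else {
    p <- suppressWarnings(cor.test(x, y, method = "kendall"))$p.value
  }
  list(tau = tau, p = p, n = n)
}

#' Weighted Pearson correlation
#'
#' Correlation from weighted means and covariances; significance by a t
#' approximation with the effective sample size
#' \eqn{n_\mathrm{eff} = (\sum w)^2 / \sum w^2}.  With uniform weights this
#' reduces exactly to the unweighted Pearson correlation.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @param w non-negative weights, `sum(w) > 0`.
#' @return list with `r`, `p`, `n_eff`; `r` is `NA` when a weighted variance
#'   is degenerate (fewer than 2 effective points).
#' @export
weightedPearson <- function(x, y, w = rep(1, length(x))) {
  stopIfNot(length(x) == length(y) && length(x) == length(w),
            "x, y, w must have equal lengths")
  stopIfNot(length(x) >= 3, "need at least 3 pairs")
  stopIfNot(all(w >= 0), "weights must be non-negative")
  stopIfNot(sum(w) > 0, "total weight must be positive")
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  n_eff <- sw^2 / sum(w^2)
  if (vx <= 0 || vy <= 0 || n_eff <= 2) {
    pdmLog("degenerate weighted variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n_eff = n_eff))
  }
  r <- sum(w * (x - mx) * (y - my)) / sw / sqrt(vx * vy)
  r <- clamp(r, -1, 1)
  tstat <- r * sqrt((n_eff - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n_eff - 2)
  list(r = r, p = p, n_eff = n_eff)
}

## one-to-one reduction: keep the pair with the highest combined weight
reduceHomologMap <- function(map, statsA = NULL, statsB = NULL,
                             weight = NULL) {
  stopIfNot(all(c("gene_a", "gene_b") %in% names(map)),
            "homolog map needs gene_a and gene_b columns")
  if (is.null(weight)) weight <- rep(1, nrow(map))
  o <- order(-weight, map$gene_a, map$gene_b)
  map <- map[o, , drop = FALSE]
  ## greedy scan: highest-weight pair claims both genes
  usedA <- character(); usedB <- character(); sel <- logical(nrow(map))
  for (i in seq_len(nrow(map))) {
    if (map$gene_a[i] %in% usedA || map$gene_b[i] %in% usedB) next
    sel[i] <- TRUE
    usedA <- c(usedA, map$gene_a[i]); usedB <- c(usedB, map$gene_b[i])
  }
  map[sel, , drop = FALSE]
}

#' Reduce a homolog map to one-to-one pairs
#'
#' Many-to-many homolog pairs are reduced by keeping, per gene, the pair
#' with the highest combined site count (columns `n_a` + `n_b` when present,
#' otherwise first occurrence).
#'
#' @param map `data.frame` with `gene_a`, `gene_b`, optional `n_a`, `n_b`.
#' @return the reduced map.
#' @export
applyHomologMap <- function(map) {
  w <- if (all(c("n_a", "n_b") %in% names(map))) map$n_a + map$n_b else NULL
  reduceHomologMap(map, weight = w)
}

#' Cross-dataset gene direction summary and overlap enrichment
#'
#' Applies the per-gene direction rule ([geneStats()]) to two fit tables,
#' forms the hyper- and hypomethylated disrupted-gene sets (`>= 1`
#' significant cytosine), tests their cross-dataset overlap, and tests
#' pathway enrichment of the directional intersections.
#'
#' @param fitsA,fitsB single-contrast fit tables.
#' @param annotation a [PanelAnnotation-class].
#' @return list with `genesA`, `genesB` ([geneStats()] tables),
#'   `hyper_overlap`, `hypo_overlap` (enrichment rows),
#'   `hyper_intersection`, `hypo_intersection` (gene ids),
#'   `hyper_pathways`, `hypo_pathways` (per-pathway gene-level Fisher).
#' @export
geneDirectionSummary <- function(fitsA, fitsB, annotation) {
  gsA <- geneStats(fitsA, annotation)
  gsB <- geneStats(fitsB, annotation)
  universe <- union(gsA$gene_id, gsB$gene_id)
  setsOf <- function(gs)
    list(hyper = gs$gene_id[gs$n_sig >= 1 & gs$direction > 0],
         hypo = gs$gene_id[gs$n_sig >= 1 & gs$direction < 0])
  sA <- setsOf(gsA); sB <- setsOf(gsB)
  pwEnrich <- function(genes) {
    g <- panelGenes(annotation)
    out <- list()
    for (pw in sort(unique(unlist(g$pathways)))) {
      pw_genes <- g$gene_id[vapply(g$pathways, function(p) pw %in% p, TRUE)]
      out[[pw]] <- fisherFromFlags(universe %in% genes,
                                   universe %in% pw_genes, label = pw)
    }
    res <- do.call(rbind, out)
    if (!is.null(res)) rownames(res) <- NULL
    res
  }
  list(genesA = gsA, genesB = gsB,
       hyper_overlap = genesetOverlap(sA$hyper, sB$hyper, universe),
       hypo_overlap = genesetOverlap(sA$hypo, sB$hypo, universe),
       hyper_intersection = intersect(sA$hyper, sB$hyper),
       hypo_intersection = intersect(sA$hypo, sB$hypo),
       hyper_pathways = pwEnrich(intersect(sA$hyper, sB$hyper)),
       hypo_pathways = pwEnrich(intersect(sA$hypo, sB$hypo)))
}

#' Effect-exacerbation odds test
#'
#' Tests whether differentially methylated sites show larger absolute effect
#' sizes in dataset A than in dataset B more often than the non-significant
#' loci do: 2x2 of \{|effect A| > |effect B|\} x \{significant vs not\},
#' two-sided Fisher.  Which dataset defines significance is configurable
#' (`"A"` — the default reading, `"union"`, or `"intersection"`).
#'
#' @param fitsA,fitsB single-contrast fit tables sharing cytosine keys.
#' @param significance significance definition for the column margin.
#' @return one-row enrichment `data.frame`.
#' @export
exacerbationTest <- function(fitsA, fitsB,
                             significance = c("A", "union", "intersection")) {
  significance <- match.arg(significance)
  fitsA <- oneContrast(fitsA); fitsB <- oneContrast(fitsB)
  shared <- intersect(fitsA$key, fitsB$key)
  stopIfNot(length(shared) > 0, "fit tables share no cytosine keys")
  a <- fitsA[match(shared, fitsA$key), ]
  b <- fitsB[match(shared, fitsB$key), ]
  sig <- switch(significance,
                A = a$significant,
                union = a$significant | b$significant,
                intersection = a$significant & b$significant)
  greater <- abs(a$pct_change) > abs(b$pct_change)
  ok <- !is.na(sig) & !is.na(greater)
  fisherFromFlags(sig[ok], greater[ok], label = "exacerbation")
}
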