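test_that("Fisher odds ratios and p values match exhaustive enumeration", {
  ## identical margins: OR 1, p 1
  r <- fisherOddsRatio(10, 90, 10, 90)
  expect_equal(r$or_value, 1)
  expect_equal(r$p, 1)
  ## diagonal table: p = 2/252 by enumeration over fixed margins
  r2 <- fisherOddsRatio(5, 0, 0, 5)
  expect_equal(r2$p, 2 / 252, tolerance = 1e-12)
  expect_true(is.infinite(r2$or_value))
  ## random sweep against the hypergeometric enumeration oracle
  set.seed(20)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    expect_equal(fisherOddsRatio(a, b, c_, d)$p,
                 enumFisherP(a, b, c_, d), tolerance = 1e-10)
    expect_equal(fisherOddsRatio(a, b, c_, d, "greater")$p,
                 enumFisherP(a, b, c_, d, "greater"), tolerance = 1e-10)
  }
  expect_error(fisherOddsRatio(0, 0, 0, 0), "all-zero")
})

test_that("the Woolf/Haldane confidence interval brackets the OR", {
  r <- fisherOddsRatio(20, 10, 8, 25)
  expect_lt(r$ci_low, r$or_value)
  expect_gt(r$ci_high, r$or_value)
  ## zero cell: Haldane correction keeps the CI finite
  r0 <- fisherOddsRatio(5, 0, 3, 7)
  expect_true(is.finite(r0$ci_low) && is.finite(r0$ci_high))
})

test_that("directional enrichment recovers a planted hypermethylation bias", {
  fx <- effectFit()          # hyper_fraction = 1
  r <- directionalEnrichment(fx$fits)
  expect_gt(r$or_value, 1)
  expect_lt(r$p, 0.05)
  ## all-hyper significant set (hypo sites exist but are null) -> infinite OR
  tbl <- syntheticFitTable("chr1", 1:20 * 10,
                           pct = c(rep(5, 10), rep(-5, 10)),
                           p = c(rep(1e-6, 10), rep(0.9, 10)))
  expect_true(is.infinite(directionalEnrichment(tbl)$or_value))
  ## no significant sites: p = 1, n_fg = 0
  tblnull <- syntheticFitTable("chr1", 1:20 * 10, pct = rep(c(-5, 5), 10),
                               p = rep(0.9, 20))
  rn <- directionalEnrichment(tblnull)
  expect_equal(rn$n_fg, 0)
  expect_equal(rn$p, 1)
})

test_that("element enrichment localizes effects planted in promoters", {
  fx <- effectFit()          # effects planted inside promoter windows
  el <- elementEnrichment(fx$fits, fx$sim$annotation)
  prom <- el[el$label == "promoter", ]
  intergenic <- el[el$label == "intergenic", ]
  expect_gt(prom$or_value, 1)
  expect_lt(prom$p, 0.05)
  expect_lt(intergenic$or_value, 1)
  ## direction-restricted foreground subsets
  hyper <- elementEnrichment(fx$fits, fx$sim$annotation, "hyper")
  expect_gt(hyper[hyper$label == "promoter", "or_value"], 1)
})

test_that("a site inside two element classes counts once per class", {
  tbl <- syntheticFitTable("chr1", c(100, 5000), pct = c(5, 5),
                           p = c(1e-6, 0.9))
  genes <- data.frame(gene_id = "G1", chrom = "chr1", tss = 100L,
                      strand = "+", window_bp = 10000L)
  el <- GenomicRanges::GRangesList(
    promoter = GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 200)),
    cgi = GenomicRanges::GRanges("chr1", IRanges::IRanges(80, 120)))
  ann <- PanelAnnotation(genes, el)
  res <- elementEnrichment(tbl, ann)
  expect_equal(res$a[res$label == "promoter"], 1)
  expect_equal(res$a[res$label == "cgi"], 1)
})

test_that("TSS bins are half-open and stratified correctly", {
  genes <- data.frame(gene_id = c("GL", "GO"), chrom = c("chr1", "chr2"),
                      tss = c(1000L, 1000L), strand = "+",
                      window_bp = 100000L, stringsAsFactors = FALSE)
  genes$pathways <- list("lysosome", character())
  ann <- PanelAnnotation(genes)
  ## distances 0, 19999, 20000, 45000 from GL's TSS
  tbl <- syntheticFitTable("chr1", c(1000, 20999, 21000, 46000),
                           pct = rep(5, 4), p = c(1e-9, 1e-9, 0.9, 0.9))
  res <- tssBinEnrichment(tbl, ann, binBp = 20000)
  ## sites at distance 0 and 19999 share bin 1; exactly 20000 opens bin 2
  expect_equal(res$n_in[res$bin == 1], 2)
  expect_equal(res$n_in[res$bin == 2], 1)
  expect_equal(res$n_in[res$bin == 3], 1)
  expect_equal(sum(res$n_in), 4)
  ## strata restrict the universe to the stratum's sites
  strata <- list(lysosome = "GL", other = "GO")
  res2 <- tssBinEnrichment(tbl, ann, binBp = 20000, strata = strata)
  expect_true(all(res2$stratum %in% c("lysosome", "other")))
  expect_equal(sum(res2$n_in[res2$stratum == "lysosome"]), 4)
})

test_that("pathway enrichment flags only the planted pathway", {
  fx <- effectFit()          # effects restricted to lysosome genes
  res <- pathwayEnrichment(fx$fits, fx$sim$annotation, "hyper")
  lys <- res[res$label == "lysosome", ]
  expect_gt(lys$or_value, 1)
  expect_lt(lys$p, 0.05)
  other <- res[res$label != "lysosome", ]
  expect_true(all(other$or_value < lys$or_value))
})

test_that("per-gene statistics follow the majority/tie-break direction rule", {
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = c("chr1", "chr2"),
                      tss = c(100L, 100L), strand = "+", window_bp = 10000L)
  ann <- PanelAnnotation(genes)
  ## G1: significant signs (+, +, -) -> majority +
  ## G2: significant signs (+, -), weighted mean fold change negative -> -
  tbl <- rbind(
    syntheticFitTable("chr1", c(100, 200, 300), pct = c(4, 3, -2),
                      p = rep(1e-8, 3), q = rep(1e-6, 3)),
    syntheticFitTable("chr2", c(100, 200, 300), pct = c(4, -3, -20),
                      p = c(1e-8, 1e-8, 1e-4), q = c(1e-6, 1e-6, 0.2)))
  gs <- geneStats(tbl, ann)
  expect_equal(gs$direction[gs$gene_id == "G1"], 1)
  ## tie: wmfc over ALL cytosines with -log10 p weights
  w <- -log10(c(1e-8, 1e-8, 1e-4))
  wmfc <- sum(w * c(4, -3, -20)) / sum(w)
  expect_lt(wmfc, 0)
  expect_equal(gs$direction[gs$gene_id == "G2"], -1)
  expect_equal(gs$wmfc[gs$gene_id == "G2"], wmfc, tolerance = 1e-10)
})

test_that("gene-level odds ratios match a direct 2x2 recomputation", {
  fx <- effectFit()
  gs <- geneStats(fx$fits, fx$sim$annotation)
  fits <- fx$fits[!is.na(fx$fits$q), ]
  gene <- assignGenes(fits, fx$sim$annotation)
  total_sig <- sum(fits$significant)
  ## bookkeeping identity: per-gene sig counts + unassigned = total
  expect_equal(sum(gs$sig_in) + sum(fits$significant[is.na(gene)]), total_sig)
  top <- gs[which.max(gs$sig_in), ]
  a <- top$sig_in; b <- top$nonsig_in
  c_ <- total_sig - a; d <- sum(!fits$significant) - b
  oracle <- fisherOddsRatio(a, b, c_, d, "greater")
  expect_equal(top$or_value, oracle$or_value)
  expect_equal(top$p_one_sided, oracle$p)
})

test_that("gene statistics are invariant to cytosine input order", {
  fx <- effectFit()
  gs1 <- geneStats(fx$fits, fx$sim$annotation)
  set.seed(21)
  shuf <- fx$fits[sample(nrow(fx$fits)), ]
  gs2 <- geneStats(shuf, fx$sim$annotation)
  expect_equal(gs1, gs2)
})

test_that("gene-set overlap counts match brute-force set arithmetic", {
  set.seed(22)
  universe <- sprintf("g%03d", 1:100)
  A <- sample(universe, 40); B <- sample(universe, 30)
  r <- genesetOverlap(A, B, universe)
  expect_equal(r$a, length(intersect(A, B)))
  expect_equal(r$b, length(setdiff(A, B)))
  expect_equal(r$c, length(setdiff(B, A)))
  expect_equal(r$d, 100 - length(union(A, B)))
  ## A = B = half the universe: perfect association
  H <- universe[1:50]
  expect_true(is.infinite(genesetOverlap(H, H, universe)$or_value))
  expect_error(genesetOverlap(A, B, character()), "empty")
})

test_that("top-site element concordance is maximal for identical fits", {
  fx <- effectFit()
  res <- topSitesElementConcordance(fx$fits, fx$fits, fx$sim$annotation,
                                    k = 500)
  expect_true(all(res$or_value == Inf | res$b + res$c == 0))
})

test_that("cross-annotation element matching agrees with a brute-force scan", {
  mkAnn <- function(starts) {
    genes <- data.frame(gene_id = "G1", chrom = "chr1", tss = 1000L,
                        strand = "+", window_bp = 1000000L)
    PanelAnnotation(genes, GenomicRanges::GRangesList(
      promoter = GenomicRanges::GRanges("chr1",
                                        IRanges::IRanges(starts, starts + 200))))
  }
  set.seed(23)
  sA <- sort(sample(seq(1000, 50000, 3000), 8))
  sB <- sA + sample(c(-1500, -500, 0, 500, 2500), 8, TRUE)
  annA <- mkAnn(sA); annB <- mkAnn(sB)
  tblA <- syntheticFitTable("chr1", sA + 100, pct = rep(5, 8),
                            p = rep(1e-6, 8))
  tblB <- syntheticFitTable("chr1", sB + 100, pct = rep(5, 8),
                            p = rep(1e-6, 8))
  res <- topSitesElementConcordance(tblA, tblB, annA, k = 8,
                                    annotationB = annB, maxgap = 1000)
  ## brute force: pairs within 1 kb gap
  matched <- sum(vapply(seq_along(sA), function(i)
    any(pmax(sB, sA[i]) - pmin(sB + 200, sA[i] + 200) <= 1000), TRUE))
  expect_equal(res$a, matched)
})

test_that("k is clamped with a warning when datasets are small", {
  fx <- effectFit()
  expect_warning(topSitesElementConcordance(fx$fits, fx$fits,
                                            fx$sim$annotation, k = 1e6),
                 "clamped")
})
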