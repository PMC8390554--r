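# Shared fixtures; heavyweight simulations are cached so several test files
# can reuse one fit.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

## tiny hand-written MethylCountSet
tinyCounts <- function() {
  M <- matrix(c(5L, 7L, 30L, 2L), 2, 2, dimnames = list(NULL, c("s1", "s2")))
  U <- matrix(c(45L, 3L, 10L, 38L), 2, 2, dimnames = list(NULL, c("s1", "s2")))
  keys <- data.frame(chrom = c("chr1", "chr2"), pos = c(100L, 250L),
                     strand = "+", context = "CpG")
  MethylCountSet(M, U, keys, data.frame(sample_id = c("s1", "s2"),
                                        group = c("case", "control")))
}

## small annotation with two genes and promoter/intergenic elements
tinyAnnotation <- function() {
  genes <- data.frame(gene_id = c("GA", "GB"), chrom = c("chr1", "chr2"),
                      tss = c(1000L, 5000L), strand = "+",
                      window_bp = 100000L, stringsAsFactors = FALSE)
  genes$pathways <- list("lysosome", "autophagy")
  el <- GenomicRanges::GRangesList(
    promoter = GenomicRanges::GRanges(c("chr1", "chr2"),
                                      IRanges::IRanges(c(1, 4000), c(1500, 5500))),
    intergenic = GenomicRanges::GRanges(c("chr1", "chr2"),
                                        IRanges::IRanges(c(50000, 50000),
                                                         c(90000, 90000))))
  PanelAnnotation(genes, el)
}

## mid-size effect simulation + fit, reused by enrichment/aging tests
effectFit <- function() cached("effectFit", {
  cfg <- simConfig(n_genes = 60, cytosines_per_gene = c(20, 40),
                   coverage_mean = 100, seed = 418,
                   affected_pathway = "lysosome",
                   effect_location = "promoter",
                   frac_affected_genes = 0.3,
                   frac_affected_cytosines = 0.8,
                   effect_pct_cv = 0.6,
                   hyper_fraction = 1,
                   age_placement = "shared_with_case",
                   frac_age_cytosines = 0.1,
                   age_slope_pct_per_year = 0.4)
  sim <- simulatePanel(cfg)
  prep <- preprocessPanel(sim$counts, sim$annotation, panelConfig())
  fits <- runDifferential(prep$counts)
  list(sim = sim, prep = prep, fits = fits)
})

## synthetic per-site fit table (no model run) for table-level statistics
syntheticFitTable <- function(chrom, pos, pct, p, q = p.adjust(p, "BH"),
                              fdr = 0.05) {
  data.frame(chrom = chrom, pos = pos, strand = "+", context = "CpG",
             key = paste(chrom, pos, "+", "CpG", sep = ":"),
             contrast = "groupcase", beta_m = pct / 10, pct_change = pct,
             sigma = 1, df_resid = 10, t_mod = pct, p = p, q = q,
             direction = sign(pct), significant = q < fdr,
             stringsAsFactors = FALSE)
}

## brute-force two-sided Fisher p by hypergeometric enumeration
enumFisherP <- function(a, b, c, d, alternative = "two.sided") {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, n, k)
  pobs <- dhyper(a, m, n, k)
  if (alternative == "greater") sum(probs[xs >= a])
  else sum(probs[probs <= pobs * (1 + 1e-7)])
}
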