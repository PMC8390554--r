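mkCounts <- function(M, U, groups = NULL, rep_group = NULL) {
  n <- ncol(M)
  ids <- sprintf("s%02d", seq_len(n))
  dimnames(M) <- dimnames(U) <- list(NULL, ids)
  keys <- data.frame(chrom = "chr1", pos = seq_len(nrow(M)) * 10L,
                     strand = "+", context = "CpG")
  sheet <- data.frame(sample_id = ids,
                      group = if (is.null(groups))
                        rep(c("case", "control"), length.out = n) else groups)
  if (!is.null(rep_group)) sheet$replicate_group <- rep_group
  MethylCountSet(M, U, keys, sheet)
}

test_that("coverage filter applies the 30x boundary exactly", {
  M <- matrix(c(10L, 10L, 10L), 1, 3)
  U <- matrix(c(19L, 20L, 50L), 1, 3)   # coverages 29, 30, 60
  mcs <- mkCounts(M, U)
  f <- coverageFilter(mcs, 30)
  expect_true(is.na(methReads(f)[1, 1]))
  expect_identical(methReads(f)[1, 2], 10L)
  expect_identical(methReads(f)[1, 3], 10L)
  f1 <- coverageFilter(mcs, 1)
  expect_false(anyNA(methReads(f1)))
})

test_that("identical replicates merge to themselves; complements are excluded", {
  M <- matrix(rep(c(5L, 20L, 40L, 12L), 2), 4, 2)
  U <- matrix(rep(c(45L, 30L, 10L, 38L), 2), 4, 2)
  mcs <- mkCounts(M, U, groups = c("case", "case"),
                  rep_group = c("g1", "g1"))
  res <- mergeReplicates(mcs, 0.9)
  expect_equal(ncol(res$counts), 1)
  expect_identical(unname(methReads(res$counts)[, 1]), M[, 1])
  expect_identical(colnames(res$counts), "g1")

  ## beta complements: r = -1 <= 0.9 -> one member excluded
  U2 <- M[, 1, drop = FALSE]; M2 <- U[, 1, drop = FALSE]
  mcs2 <- mkCounts(cbind(M[, 1], M2), cbind(U[, 1], U2),
                   groups = c("case", "case"), rep_group = c("g1", "g1"))
  res2 <- mergeReplicates(mcs2, 0.9)
  expect_gt(nrow(res2$report$excluded_samples), 0)
  expect_equal(ncol(res2$counts), 1)
})

test_that("merged counts equal the rounded mean of replicate counts", {
  set.seed(8)
  for (rep in 1:5) {
    n_sites <- 20
    base <- matrix(rpois(n_sites, 40), n_sites, 1)
    M1 <- base + rpois(n_sites, 2); M2 <- base + rpois(n_sites, 2)
    U1 <- matrix(rpois(n_sites, 60), n_sites, 1)
    U2 <- U1 + rpois(n_sites, 2)
    mcs <- mkCounts(cbind(M1, M2), cbind(U1, U2),
                    groups = c("case", "case"), rep_group = c("g", "g"))
    res <- mergeReplicates(mcs, 0.5)
    expect_identical(unname(methReads(res$counts)[, 1]),
                     as.integer(floor((M1 + M2) / 2 + 0.5)))
    expect_identical(unname(unmethReads(res$counts)[, 1]),
                     as.integer(floor((U1 + U2) / 2 + 0.5)))
  }
})

test_that("site filters apply call-rate, all-zero, SNP and stable rules in order", {
  n <- 10   # samples
  mk <- function(nm) matrix(nm, 1, n)
  ## site A: observed in 6/10 (60%) -> callrate fail at 0.7
  MA <- mk(c(rep(10L, 6), rep(NA, 4))); UA <- mk(c(rep(10L, 6), rep(NA, 4)))
  ## site B: all observed calls zero
  MB <- mk(rep(0L, n)); UB <- mk(rep(50L, n))
  ## site C: mid-methylation but sits on a masked SNP
  MC <- mk(rep(25L, n)); UC <- mk(rep(25L, n))
  ## site D: 5/10 samples at exactly 100% -> stable >= 0.5 (inclusive)
  MD <- mk(c(rep(50L, 5), rep(25L, 5))); UD <- mk(c(rep(0L, 5), rep(25L, 5)))
  ## site E: survives everything
  ME <- mk(rep(20L, n)); UE <- mk(rep(30L, n))
  M <- rbind(MA, MB, MC, MD, ME); U <- rbind(UA, UB, UC, UD, UE)
  ids <- sprintf("s%02d", 1:n)
  dimnames(M) <- dimnames(U) <- list(NULL, ids)
  keys <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                     strand = "+", context = "CpG")
  mcs <- MethylCountSet(M, U, keys,
                        data.frame(sample_id = ids,
                                   group = rep(c("case", "control"), 5)))
  ann <- PanelAnnotation(data.frame(gene_id = "G1", chrom = "chr1", tss = 1L,
                                    strand = "+", window_bp = 1000L),
                         snpMask = GenomicRanges::GRanges(
                           "chr1", IRanges::IRanges(30, 30)))
  res <- siteFilters(mcs, ann)
  st <- res$report$stages
  expect_identical(st$stage, c("callrate", "allzero", "snp_mask", "stable"))
  expect_identical(st$removed, rep(1L, 4))
  expect_identical(rownames(res$counts), "chr1:50:+:CpG")
  rs <- res$report$removed_sites
  expect_identical(rs$reason[match(paste0("chr1:", c(10, 20, 30, 40), ":+:CpG"),
                                   rs$key)],
                   c("callrate", "allzero", "snp_mask", "stable"))
})

test_that("site filter boundaries are inclusive as stated", {
  n <- 100
  obs69 <- c(rep(20L, 69), rep(NA, 31))
  obs70 <- c(rep(20L, 70), rep(NA, 30))
  M <- rbind(obs69, obs70); U <- rbind(obs69, obs70)
  ids <- sprintf("s%03d", 1:n)
  dimnames(M) <- dimnames(U) <- list(NULL, ids)
  keys <- data.frame(chrom = "chr1", pos = c(10L, 20L), strand = "+",
                     context = "CpG")
  mcs <- MethylCountSet(M, U, keys,
                        data.frame(sample_id = ids, group = "case"))
  res <- siteFilters(mcs, stages = "callrate")
  expect_identical(rownames(res$counts), "chr1:20:+:CpG")
})

test_that("quantile normalization matches its definition", {
  ## permuted columns -> identical multisets
  M <- cbind(c(10L, 40L, 90L), c(90L, 10L, 40L))
  U <- cbind(c(30L, 30L, 30L), c(30L, 30L, 30L))
  mcs <- mkCounts(M, U)
  qn <- quantileNormalizeCounts(mcs)
  expect_identical(sort(unname(methReads(qn)[, 1])),
                   sort(unname(methReads(qn)[, 2])))

  ## identical columns are a fixed point
  M2 <- cbind(c(10L, 40L, 90L), c(10L, 40L, 90L))
  qn2 <- quantileNormalizeCounts(mkCounts(M2, U))
  expect_identical(methReads(qn2), methReads(mkCounts(M2, U)))

  ## 3x3 hand-executed rank/mean table:
  ## cols sorted: (10,40,90), (5,50,95), (20,41,80); row means (35/3+..) =
  ## ranks 1..3 -> reference quantiles (11.667, 43.667, 88.333)
  M3 <- cbind(c(10L, 40L, 90L), c(50L, 5L, 95L), c(80L, 20L, 41L))
  qn3 <- quantileNormalizeCounts(mkCounts(M3, matrix(100L, 3, 3)))
  ref <- floor(c(mean(c(10, 5, 20)), mean(c(40, 50, 41)),
                 mean(c(90, 95, 80))) + 0.5)
  expect_identical(unname(methReads(qn3)[, 1]), as.integer(ref[c(1, 2, 3)]))
  expect_identical(unname(methReads(qn3)[, 2]), as.integer(ref[c(2, 1, 3)]))
  expect_identical(unname(methReads(qn3)[, 3]), as.integer(ref[c(3, 1, 2)]))
})

test_that("quantile normalization preserves within-column rank order", {
  set.seed(5)
  M <- matrix(as.integer(rpois(200, 50)), 50, 4)
  U <- matrix(as.integer(rpois(200, 50)), 50, 4)
  qn <- quantileNormalizeCounts(mkCounts(M, U))
  for (j in 1:4)
    expect_true(all(diff(methReads(qn)[order(M[, j]), j]) >= 0))
})

test_that("a planted extreme sample is the one PCA flags", {
  ## panel large enough that correlated structure, not counting noise,
  ## dominates the top components
  sim <- simulatePanel(simConfig(n_genes = 60, cytosines_per_gene = c(25, 35),
                                 n_outlier_samples = 1, seed = 41))
  filt <- coverageFilter(sim$counts, 30)
  res <- pcaOutliers(filt, 3)
  expect_identical(res$excluded, sim$truth$outlier_samples)
})

test_that("homogeneous data yield no PCA outliers in most seeds", {
  hits <- vapply(1:8, function(s) {
    sim <- simulateNull(simConfig(n_genes = 10, cytosines_per_gene = c(8, 10),
                                  seed = 200 + s, n_batches = 1,
                                  n_latent_factors = 0))
    length(pcaOutliers(coverageFilter(sim$counts, 30), 3)$excluded)
  }, 0)
  expect_gte(mean(hits == 0), 0.75)
})

test_that("a duplicated sample is never a PCA outlier", {
  sim <- simulateNull(simConfig(n_genes = 10, cytosines_per_gene = c(8, 10),
                                seed = 77, n_batches = 1,
                                n_latent_factors = 0))
  M <- methReads(sim$counts); U <- unmethReads(sim$counts)
  M2 <- cbind(M, dup = M[, 1]); U2 <- cbind(U, dup = U[, 1])
  sheet <- rbind(sampleSheet(sim$counts),
                 data.frame(sample_id = "dup", group = "case",
                            age = 50, sex = "M", pmi = 10, batch = "B1",
                            replicate_group = NA))
  mcs <- MethylCountSet(M2, U2, cytosineKeys(sim$counts), sheet)
  res <- pcaOutliers(coverageFilter(mcs, 30), 3)
  expect_false("dup" %in% res$excluded)
})

test_that("the preprocessing chain telescopes and orders stages correctly", {
  sim <- simulatePanel(simConfig(n_genes = 15, cytosines_per_gene = c(8, 12),
                                 n_replicate_pairs = 2, seed = 51))
  res <- preprocessPanel(sim$counts, sim$annotation, panelConfig())
  st <- res$report$stages
  expect_identical(st$stage, c("coverage", "replicate_merge", "callrate",
                               "allzero", "stable", "pca_outliers"))
  expect_true(all(st$before - st$removed == st$after))
  site_stages <- st[st$unit == "sites", ]
  expect_true(all(diff(c(site_stages$before[1], site_stages$after)) <= 0))
  expect_equal(nrow(res$counts), site_stages$after[nrow(site_stages)])
})
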