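test_that("counts tables round-trip through read/write", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tstrand\tcontext\ts1.M\ts1.U\ts2.M\ts2.U",
    "chr1\t100\t+\tCpG\t5\t45\t30\t10",
    "chr2\t250\t+\tCpG\t7\t3\t\t"), path)
  mcs <- readCounts(path)
  expect_identical(dim(methReads(mcs)), c(2L, 2L))
  expect_identical(methReads(mcs)["chr1:100:+:CpG", "s1"], 5L)
  expect_identical(unmethReads(mcs)["chr1:100:+:CpG", "s2"], 10L)
  expect_true(is.na(methReads(mcs)["chr2:250:+:CpG", "s2"]))

  out <- withr::local_tempfile(fileext = ".tsv")
  writeCounts(mcs, out)
  expect_identical(readLines(path), readLines(out))

  ## randomized round trip
  sim <- simulatePanel(simConfig(n_genes = 4, cytosines_per_gene = c(3, 6),
                                 n_case = 3, n_control = 3, seed = 5))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeCounts(sim$counts, p2)
  back <- readCounts(p2)
  expect_identical(methReads(back), methReads(sim$counts))
  expect_identical(unmethReads(back), unmethReads(sim$counts))
})

test_that("malformed or duplicated count rows are rejected with location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tstrand\tcontext\ts1.M\ts1.U",
    "chr1\t100\t+\tCpG\t5\t45",
    "chr1\t200\t+\tCpG\t5"), path)
  expect_error(readCounts(path), "line 3")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tstrand\tcontext\ts1.M\ts1.U",
    "chr1\t100\t+\tCpG\t5\t45",
    "chr1\t100\t+\tCpG\t6\t40"), dup)
  expect_error(readCounts(dup), "duplicate")
})

test_that("MethylCountSet enforces its invariants", {
  M <- matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "b")))
  U <- matrix(1L, 2, 2, dimnames = list(NULL, c("a", "b")))
  keys <- data.frame(chrom = "chr1", pos = 1:2, strand = "+", context = "CpG")
  sheet <- data.frame(sample_id = c("a", "b"), group = "case")
  expect_s4_class(MethylCountSet(M, U, keys, sheet), "MethylCountSet")
  expect_error(MethylCountSet(M, U, data.frame(chrom = "chr1", pos = c(1, 1),
                                               strand = "+", context = "CpG"),
                              sheet), "duplicate")
  Mneg <- M; Mneg[1] <- -1L
  expect_error(validObject(MethylCountSet(Mneg, U, keys, sheet)),
               "non-negative")
  Mna <- M; Mna[1] <- NA_integer_  # NA in M only -> invalid
  expect_error(validObject(MethylCountSet(Mna, U, keys, sheet)), "missing")
})

test_that("BED intervals use 0-based half-open input coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tpromoter", bed)
  genes <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\ttss\tstrand\twindow_bp\tpathways",
               "G1\tchr1\t150\t+\t1000\tlysosome"), genes)
  ann <- readPanelAnnotation(genes, bed)
  gr <- panelElements(ann)$promoter
  expect_equal(GenomicRanges::start(gr), 100)
  expect_equal(BiocGenerics::end(gr), 200)

  ## point membership: 1-based pos p is inside [s,e) iff s < p <= e
  site99 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(99, 99))
  site100 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 100))
  site200 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 200))
  site201 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 201))
  expect_false(IRanges::overlapsAny(site99, gr))
  expect_true(IRanges::overlapsAny(site100, gr))
  expect_true(IRanges::overlapsAny(site200, gr))
  expect_false(IRanges::overlapsAny(site201, gr))
})

test_that("interval membership matches a brute-force point scan", {
  set.seed(42)
  for (rep in 1:5) {
    n_iv <- 20
    s <- sample(0:500, n_iv, TRUE)
    e <- s + sample(1:100, n_iv, TRUE)
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(paste("chr1", s, e, "exon", sep = "\t"), bed)
    gr <- padlockDM:::readBedIntervals(bed)
    pts <- sample(1:650, 80)
    inside_bf <- vapply(pts, function(p) any(s < p & p <= e), TRUE)
    inside_gr <- IRanges::overlapsAny(
      GenomicRanges::GRanges("chr1", IRanges::IRanges(pts, pts)), gr)
    expect_identical(inside_gr, inside_bf)
  }
})

test_that("annotation validation rejects bad intervals and pathways", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t200\t200\tpromoter", bed)
  genes <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\ttss\tstrand\twindow_bp\tpathways",
               "G1\tchr1\t150\t+\t1000\tlysosome"), genes)
  expect_error(readPanelAnnotation(genes, bed), "end <= start")

  genes2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\ttss\tstrand\twindow_bp\tpathways",
               "G1\tchr1\t150\t+\t1000\tmitophagy"), genes2)
  expect_error(readPanelAnnotation(genes2), "mitophagy")
})

test_that("overlapping same-class elements behave as a union", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", tss = 100L,
                      strand = "+", window_bp = 1000L)
  el <- GenomicRanges::GRangesList(
    promoter = GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(c(50, 120), c(150, 300))))
  ann <- PanelAnnotation(genes, el)
  pts <- 1:400
  inside <- IRanges::overlapsAny(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(pts, pts)),
    panelElements(ann)$promoter)
  expect_identical(inside, (pts >= 50 & pts <= 150) | (pts >= 120 & pts <= 300))
})

test_that("config defaults match the study thresholds and validate", {
  cfg <- panelConfig()
  expect_equal(cfg$min_coverage, 30)
  expect_equal(cfg$min_call_rate, 0.7)
  expect_equal(cfg$stable_fraction, 0.5)
  expect_equal(cfg$outlier_sd, 3)
  expect_equal(cfg$replicate_min_r, 0.9)
  expect_equal(cfg$shrink_factor, 1000)
  expect_equal(cfg$shrink_factor_cph, 2000)
  expect_equal(cfg$sv_var_threshold, 0.05)
  expect_equal(cfg$irls_max_iter, 100)
  expect_equal(cfg$fdr_q, 0.05)
  expect_equal(cfg$tss_bin_bp, 20000)
  expect_error(panelConfig(bogus = 1), "unknown config")
  expect_error(panelConfig(fdr_q = 1.5), "fdr_q")

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("min_coverage: 20", "fdr_q: 0.1"), yml)
  cfg2 <- readPanelConfig(yml)
  expect_equal(cfg2$min_coverage, 20)
  expect_equal(cfg2$fdr_q, 0.1)
  expect_equal(cfg2$shrink_factor, 1000)
  expect_match(configHash(cfg), "^[0-9a-f]{32}$")
  expect_false(configHash(cfg) == configHash(cfg2))
})

test_that("sample sheets attach to counts and reject mismatches", {
  mcs <- tinyCounts()
  csv <- withr::local_tempfile(fileext = ".csv")
  writeSampleSheet(mcs, csv)
  back <- readSampleSheet(csv, mcs)
  expect_identical(sampleSheet(back)$group, c("case", "control"))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group", "s1,case", "sX,control"), bad)
  expect_error(readSampleSheet(bad, mcs), "does not match")
})
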