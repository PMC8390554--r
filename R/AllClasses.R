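#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList seqnames start strand
#'   findOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowRanges colData colData<-
NULL

VALID_CONTEXTS <- c("CpG", "CpH")
VALID_PATHWAYS <- c("autophagy", "CMA", "lysosome", "macroautophagy",
                    "selective_autophagy")
VALID_ELEMENTS <- c("promoter", "1to5kb", "5UTR", "exon", "intron", "3UTR",
                    "intergenic", "cgi", "shore", "shelf", "open_sea",
                    "active_promoter", "active_enhancer", "poised_enhancer")

#' Container for cytosine-level methylation counts
#'
#' `MethylCountSet` extends [SummarizedExperiment::RangedSummarizedExperiment]
#' with paired integer assays `M` (methylated reads) and `U` (unmethylated
#' reads), one row per cytosine and one column per sample.  Row ranges are
#' width-1 `GRanges` carrying the sequence `context` (`"CpG"` or `"CpH"`);
#' column data hold the sample sheet (at minimum `sample_id` and `group`).
#' Missing observations are `NA` in both `M` and `U`; a covered cell is never
#' `NA` in only one of the two.
#'
#' @slot .nodata See `RangedSummarizedExperiment`; no additional slots.
#' @aliases MethylCountSet-class
#' @exportClass MethylCountSet
setClass("MethylCountSet",
         contains = "RangedSummarizedExperiment")

setValidity("MethylCountSet", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("M", "U") %in% an))
    msg <- c(msg, "assays must include 'M' and 'U'")
  else {
    M <- assay(object, "M"); U <- assay(object, "U")
    if (!identical(dim(M), dim(U)))
      msg <- c(msg, "'M' and 'U' must have identical dimensions")
    if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
      msg <- c(msg, "counts must be non-negative")
    if (any(is.na(M) != is.na(U)))
      msg <- c(msg, "missingness of 'M' and 'U' must agree cellwise")
  }
  ctx <- rowRanges(object)$context
  if (is.null(ctx) || !all(ctx %in% VALID_CONTEXTS))
    msg <- c(msg, "rowRanges()$context must be 'CpG' or 'CpH'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate cytosine keys")
  cd <- colData(object)
  if (!"sample_id" %in% colnames(cd))
    msg <- c(msg, "colData must contain 'sample_id'")
  else if (anyDuplicated(cd$sample_id))
    msg <- c(msg, "sample_id values must be unique")
  if ("age" %in% colnames(cd) && any(cd$age < 0, na.rm = TRUE))
    msg <- c(msg, "age must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylCountSet
#'
#' @param M,U integer matrices of methylated / unmethylated read counts
#'   (cytosines x samples); `NA` marks missing cells and must agree between
#'   the two.
#' @param keys `data.frame` with columns `chrom`, `pos` (1-based), `strand`
#'   (`"+"`/`"-"`), `context` (`"CpG"`/`"CpH"`), one row per row of `M`.
#' @param sampleData `data.frame` or `DataFrame` of per-sample covariates;
#'   must contain `sample_id` matching `colnames(M)` (created from column
#'   names when absent).
#'
#' @return A validated [MethylCountSet-class] object.
#' @examples
#' M <- matrix(5:8, 2, 2, dimnames = list(NULL, c("s1", "s2")))
#' U <- matrix(10L, 2, 2, dimnames = list(NULL, c("s1", "s2")))
#' keys <- data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                    strand = "+", context = "CpG")
#' mcs <- MethylCountSet(M, U, keys,
#'                       data.frame(sample_id = c("s1", "s2"),
#'                                  group = c("case", "control")))
#' betaValues(mcs)
#' @export
MethylCountSet <- function(M, U, keys, sampleData) {
  M <- as.matrix(M); U <- as.matrix(U)
  storage.mode(M) <- "integer"; storage.mode(U) <- "integer"
  stopIfNot(is.data.frame(keys) &&
              all(c("chrom", "pos", "strand", "context") %in% names(keys)),
            "keys must have chrom/pos/strand/context columns")
  stopIfNot(all(keys$pos >= 1), "cytosine positions must be >= 1")
  if (missing(sampleData) || is.null(sampleData))
    sampleData <- data.frame(sample_id = colnames(M))
  sampleData <- as.data.frame(sampleData)
  if (!"sample_id" %in% names(sampleData))
    sampleData$sample_id <- colnames(M)
  rr <- GRanges(keys$chrom, IRanges(keys$pos, width = 1),
                strand = keys$strand, context = keys$context)
  ids <- cytosineKey(keys$chrom, keys$pos, keys$strand, keys$context)
  dup <- duplicated(ids)
  stopIfNot(!any(dup), "duplicate cytosine keys (first: %s)", ids[dup][1])
  names(rr) <- ids
  rownames(M) <- rownames(U) <- ids
  colnames(M) <- colnames(U) <- sampleData$sample_id
  se <- SummarizedExperiment(assays = list(M = M, U = U), rowRanges = rr,
                             colData = DataFrame(sampleData,
                                                 row.names = sampleData$sample_id))
  new("MethylCountSet", se)
}

#' Annotation of a targeted methylation panel
#'
#' Holds the gene records of the panel (TSS, probed window, pathway
#' memberships), named genomic-element interval sets, and a SNP mask, all as
#' `GRanges`/`GRangesList` using 1-based closed coordinates internally (BED
#' input is converted at the reader boundary).
#'
#' @slot genes `data.frame` with columns `gene_id`, `chrom`, `tss` (1-based),
#'   `strand`, `window_bp`, `pathways` (list column of pathway names drawn
#'   from the closed set autophagy/CMA/lysosome/macroautophagy/
#'   selective_autophagy) and logical `gwas_flag`.
#' @slot elements named `GRangesList` of genomic-element interval sets.
#' @slot snpMask `GRanges` of positions to exclude (common SNPs).
#' @aliases PanelAnnotation-class
#' @exportClass PanelAnnotation
setClass("PanelAnnotation",
         representation(genes = "data.frame",
                        elements = "GRangesList",
                        snpMask = "GRanges"))

setValidity("PanelAnnotation", function(object) {
  msg <- character()
  g <- object@genes
  need <- c("gene_id", "chrom", "tss", "strand", "window_bp")
  if (!all(need %in% names(g)))
    msg <- c(msg, paste("genes must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(g$gene_id)) msg <- c(msg, "gene_id values must be unique")
    if (any(g$tss < 1)) msg <- c(msg, "tss must be 1-based positive")
    if (!is.null(g$pathways)) {
      pw <- unique(unlist(g$pathways))
      bad <- setdiff(pw, VALID_PATHWAYS)
      if (length(bad))
        msg <- c(msg, paste("unknown pathway label(s):", paste(bad, collapse = ", ")))
    }
  }
  if (length(object@elements)) {
    bad <- setdiff(names(object@elements), VALID_ELEMENTS)
    if (length(bad))
      msg <- c(msg, paste("unknown element class(es):", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PanelAnnotation
#'
#' @param genes see [PanelAnnotation-class]; `pathways` may be a list column
#'   or a comma-separated character column (split automatically).
#' @param elements named `GRangesList` (or list of `GRanges`) of element
#'   intervals, 1-based closed.
#' @param snpMask `GRanges` of masked positions (may be empty).
#' @return A validated [PanelAnnotation-class] object.
#' @export
PanelAnnotation <- function(genes, elements = GRangesList(), snpMask = GRanges()) {
  genes <- as.data.frame(genes)
  if (!is.null(genes$pathways) && is.character(genes$pathways))
    genes$pathways <- lapply(strsplit(genes$pathways, ","),
                             function(p) setdiff(trimws(p), ""))
  if (is.null(genes$pathways)) genes$pathways <- vector("list", nrow(genes))
  if (is.null(genes$gwas_flag)) genes$gwas_flag <- FALSE
  if (!is(elements, "GRangesList")) elements <- GRangesList(elements)
  elements <- GRangesList(lapply(elements, sort))
  snpMask <- sort(snpMask)
  new("PanelAnnotation", genes = genes, elements = elements, snpMask = snpMask)
}

#' @describeIn PanelAnnotation-class gene table accessor
#' @param x a `PanelAnnotation`
#' @export
panelGenes <- function(x) x@genes

#' @describeIn PanelAnnotation-class element interval accessor
#' @export
panelElements <- function(x) x@elements

#' @describeIn PanelAnnotation-class SNP mask accessor
#' @export
panelSnpMask <- function(x) x@snpMask

setMethod("show", "PanelAnnotation", function(object) {
  cat("PanelAnnotation with", nrow(object@genes), "genes,",
      length(object@elements), "element classes,",
      length(object@snpMask), "masked intervals\n")
})

#' Methylated read counts
#' @param x a [MethylCountSet-class]
#' @return integer matrix
#' @export
methReads <- function(x) assay(x, "M")

#' Unmethylated read counts
#' @param x a [MethylCountSet-class]
#' @return integer matrix
#' @export
unmethReads <- function(x) assay(x, "U")

#' Total read coverage per cell
#' @param x a [MethylCountSet-class]
#' @return integer matrix `M + U`
#' @export
totalReads <- function(x) assay(x, "M") + assay(x, "U")

#' Beta values B = M / (M + U)
#'
#' @param x a [MethylCountSet-class]
#' @param minCoverage cells with coverage below this are returned as `NA`
#'   (coverage 0 is always `NA`).
#' @return numeric matrix in `[0, 1]` with `NA` for missing cells
#' @export
betaValues <- function(x, minCoverage = 1L) {
  M <- assay(x, "M"); U <- assay(x, "U")
  tot <- M + U
  B <- M / tot
  B[!is.na(tot) & tot < minCoverage] <- NA_real_
  B
}

#' Cytosine key table
#' @param x a [MethylCountSet-class]
#' @return `data.frame` with chrom/pos/strand/context, rownames = keys
#' @export
cytosineKeys <- function(x) {
  rr <- rowRanges(x)
  data.frame(chrom = as.character(seqnames(rr)),
             pos = start(rr),
             strand = as.character(strand(rr)),
             context = rr$context,
             row.names = names(rr))
}

#' Sample sheet accessor
#' @param x a [MethylCountSet-class]
#' @return `data.frame` of per-sample covariates
#' @export
sampleSheet <- function(x) as.data.frame(colData(x))
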