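#' Read a cytosine count table
#'
#' The table is tab-separated with a header line: columns `chrom`, `pos`,
#' `strand`, `context`, then one `<sample>.M` / `<sample>.U` column pair per
#' sample.  Empty fields mark missing cells.  Lines starting with `#` are
#' ignored (run metadata).
#'
#' @param path counts TSV file.
#' @return a [MethylCountSet-class] (no sample covariates beyond ids; attach a
#'   sample sheet with [readSampleSheet()]).
#' @seealso [writeCounts()]
#' @export
readCounts <- function(path) {
  stopIfNot(file.exists(path), "counts file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                            quote = "")
  bad <- which(nf != nf[1])
  stopIfNot(!length(bad), "malformed row in %s: line %d has %d fields, expected %d",
            path, bad[1], nf[bad[1]], nf[1])
  tab <- read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  fixed <- c("chrom", "pos", "strand", "context")
  stopIfNot(identical(names(tab)[1:4], fixed),
            "counts file must start with columns chrom, pos, strand, context")
  rest <- names(tab)[-(1:4)]
  stopIfNot(length(rest) %% 2 == 0 &&
              all(grepl("\\.M$", rest[c(TRUE, FALSE)])) &&
              all(grepl("\\.U$", rest[c(FALSE, TRUE)])),
            "sample columns must be interleaved <sample>.M, <sample>.U pairs")
  samples <- sub("\\.M$", "", rest[c(TRUE, FALSE)])
  stopIfNot(identical(samples, sub("\\.U$", "", rest[c(FALSE, TRUE)])),
            "mismatched .M/.U sample column pairs")
  M <- as.matrix(tab[rest[c(TRUE, FALSE)]])
  U <- as.matrix(tab[rest[c(FALSE, TRUE)]])
  colnames(M) <- colnames(U) <- samples
  ## a cell observed in only one of M/U is malformed input
  stopIfNot(!any(is.na(M) != is.na(U)),
            "cells with exactly one of M/U missing in %s", path)
  MethylCountSet(M, U, tab[fixed],
                 data.frame(sample_id = samples, stringsAsFactors = FALSE))
}

#' Write a cytosine count table
#'
#' Inverse of [readCounts()]; missing cells are written as empty fields.
#'
#' @param x a [MethylCountSet-class].
#' @param path output TSV path.
#' @param config_hash,seed optional run metadata written as a `#` comment line.
#' @return the path, invisibly.
#' @export
writeCounts <- function(x, path, config_hash = NULL, seed = NULL) {
  keys <- cytosineKeys(x)
  M <- methReads(x); U <- unmethReads(x)
  out <- keys
  for (s in colnames(M)) {
    out[[paste0(s, ".M")]] <- M[, s]
    out[[paste0(s, ".U")]] <- U[, s]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash) || !is.null(seed))
    writeLines(sprintf("# config_hash=%s seed=%s",
                       ifelse(is.null(config_hash), "NA", config_hash),
                       ifelse(is.null(seed), "NA", as.character(seed))), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with at least `sample_id` and `group`; recognised optional columns are
#' `age`, `sex`, `pmi`, `batch`, `replicate_group`, plus any extra numeric
#' covariates.
#'
#' @param path CSV file.
#' @param counts optional [MethylCountSet-class]; when given, the sheet is
#'   checked to cover exactly its samples and is attached to a copy of it.
#' @return a `data.frame`, or a `MethylCountSet` with the sheet attached when
#'   `counts` is supplied.
#' @export
readSampleSheet <- function(path, counts = NULL) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  stopIfNot(all(c("sample_id", "group") %in% names(sheet)),
            "sample sheet must have sample_id and group columns")
  stopIfNot(!anyDuplicated(sheet$sample_id), "duplicate sample_id in sheet")
  if ("age" %in% names(sheet))
    stopIfNot(all(sheet$age >= 0, na.rm = TRUE), "age must be non-negative")
  if (is.null(counts)) return(sheet)
  stopIfNot(setequal(sheet$sample_id, colnames(counts)),
            "sample sheet does not match count matrix samples")
  sheet <- sheet[match(colnames(counts), sheet$sample_id), , drop = FALSE]
  colData(counts) <- DataFrame(sheet, row.names = sheet$sample_id)
  validObject(counts)
  counts
}

#' Write a sample sheet
#' @param sheet `data.frame` (or the `colData` of a [MethylCountSet-class]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSampleSheet <- function(sheet, path) {
  if (is(sheet, "MethylCountSet")) sheet <- sampleSheet(sheet)
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## BED (0-based half-open) -> 1-based closed GRanges; the only coordinate
## conversion seam in the package
readBedIntervals <- function(path) {
  cols <- utils::count.fields(path, sep = "\t", comment.char = "#")
  stopIfNot(all(cols >= 3), "BED file %s has a line with < 3 fields", path)
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("chrom", "start", "end")
  bad <- which(tab$end <= tab$start)
  stopIfNot(!length(bad),
            "BED interval with end <= start in %s (line %d)", path, bad[1])
  stopIfNot(all(tab$start >= 0), "negative BED start in %s", path)
  gr <- GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end))
  if (ncol(tab) >= 4) gr$name <- as.character(tab[[4]])
  sort(gr)
}

writeBedIntervals <- function(gr, path, name = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,
                   end = BiocGenerics::end(gr))
  if (!is.null(gr$name)) df$name <- gr$name
  else if (!is.null(name)) df$name <- name
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read panel annotation files
#'
#' @param genes_path TSV with columns `gene_id`, `chrom`, `tss` (1-based),
#'   `strand`, `window_bp`, optional `pathways` (comma-separated, drawn from
#'   autophagy/CMA/lysosome/macroautophagy/selective_autophagy) and
#'   `gwas_flag`.
#' @param elements_path BED (0-based half-open) whose name column is the
#'   element class; may be `NULL`.
#' @param mask_path BED of SNP-masked intervals; may be `NULL`.
#' @return a [PanelAnnotation-class].
#' @export
readPanelAnnotation <- function(genes_path, elements_path = NULL,
                                mask_path = NULL) {
  for (p in c(genes_path, elements_path, mask_path))
    stopIfNot(file.exists(p), "annotation file not found: %s", p)
  genes <- read.delim(genes_path, comment.char = "#", stringsAsFactors = FALSE)
  elements <- GRangesList()
  if (!is.null(elements_path)) {
    gr <- readBedIntervals(elements_path)
    stopIfNot(!is.null(gr$name), "elements BED needs a name (class) column")
    elements <- GRangesList(lapply(split(gr, gr$name), function(g) {
      g$name <- NULL
      g
    }))
  }
  mask <- if (is.null(mask_path)) GRanges() else {
    g <- readBedIntervals(mask_path)
    g$name <- NULL
    g
  }
  PanelAnnotation(genes, elements, mask)
}

#' Write the gene table of a panel annotation
#' @param annotation a [PanelAnnotation-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writePanelGenes <- function(annotation, path) {
  g <- panelGenes(annotation)
  g$pathways <- vapply(g$pathways, paste, "", collapse = ",")
  write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
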