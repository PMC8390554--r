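#' @importFrom stats median mad qnorm pnorm pt qt sd var cor prcomp rbeta
#'   rbinom rnbinom rnorm runif complete.cases lm.wfit lm.fit p.adjust
#'   fisher.test ks.test t.test cor.test pbeta plogis qlogis setNames
#'   coef quantile dhyper
#' @importFrom utils read.delim write.table head modifyList
NULL

## round half away from zero at .5 (classic "half-up" for non-negative counts)
roundHalfUp <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## stage messages go to stderr so table output streams stay clean
pdmLog <- function(...) message("[padlockDM] ", sprintf(...))

## key string uniquely identifying a cytosine
cytosineKey <- function(chrom, pos, strand, context) {
  paste(chrom, pos, strand, context, sep = ":")
}

stopIfNot <- function(cond, fmt, ...) {
  if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
}

## derive a bounded child seed for a named simulation stream from the master
## seed; fixed offsets keep streams stable when stages are added
streamSeed <- function(seed, stream) {
  offsets <- c(baseline = 101L, layout = 211L, effects = 307L,
               samples = 401L, coverage = 503L, counts = 601L,
               replicates = 701L, outliers = 809L, annotation = 907L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 1000 + off) %% .Machine$integer.max)
}

writeTsv <- function(df, path, config_hash = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash) || !is.null(seed)) {
    writeLines(sprintf("# config_hash=%s seed=%s",
                       ifelse(is.null(config_hash), "NA", config_hash),
                       ifelse(is.null(seed), "NA", as.character(seed))), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}
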