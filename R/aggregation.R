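#' Normalized rank matrix from per-dataset gene p values
#'
#' Within each dataset, genes are ranked by their enrichment p value
#' (average ranks for ties) and the rank is divided by the dataset's gene
#' count, giving values in `(0, 1]`.  Genes absent from a dataset receive
#' the uninformative-worst rank 1.
#'
#' @param pvalue_lists named list of named numeric vectors (gene -> p), one
#'   per dataset; each dataset must rank at least 2 genes.
#' @return numeric matrix, genes x datasets, values in `(0, 1]`.
#' @export
normalizeRanks <- function(pvalue_lists) {
  stopIfNot(length(pvalue_lists) >= 1, "need at least one dataset")
  for (d in seq_along(pvalue_lists))
    stopIfNot(length(pvalue_lists[[d]]) >= 2,
              "dataset %d ranks fewer than 2 genes", d)
  genes <- sort(unique(unlist(lapply(pvalue_lists, names))))
  R <- matrix(1, length(genes), length(pvalue_lists),
              dimnames = list(genes, names(pvalue_lists)))
  for (d in seq_along(pvalue_lists)) {
    p <- pvalue_lists[[d]]
    R[names(p), d] <- rank(p, ties.method = "average") / length(p)
  }
  R
}

#' Robust rank aggregation score of one rank vector
#'
#' For a sorted vector of normalized ranks \eqn{r_{(1)} \le \dots \le
#' r_{(k)}}, computes for each j the probability that at least j of k
#' independent Uniform(0,1) values fall at or below \eqn{r_{(j)}} — the
#' Beta(j, k - j + 1) CDF at \eqn{r_{(j)}} — and returns the minimum over j.
#' Small values flag items ranked consistently higher across lists than
#' expected by chance.
#'
#' @param r ascending numeric vector in `(0, 1]`.
#' @param k number of lists (defaults to `length(r)`).
#' @return rho score in `(0, 1]`.
#' @examples
#' rraRho(c(0.02, 0.3, 0.9))
#' @export
rraRho <- function(r, k = length(r)) {
  stopIfNot(!is.unsorted(r), "rank vector must be ascending")
  stopIfNot(all(r > 0 & r <= 1), "normalized ranks must be in (0, 1]")
  stopIfNot(length(r) == k, "length(r) must equal k")
  j <- seq_len(k)
  min(pbeta(r, j, k - j + 1))
}

#' Aggregate per-dataset gene rankings
#'
#' Applies [rraRho()] to each gene's rank vector and corrects with the
#' Bonferroni-style bound `p_adj = min(1, rho * k)` where k is the number of
#' datasets.  Output is sorted by `p_adj`, ties broken by `gene_id`.
#'
#' @param rank_matrix genes x datasets matrix from [normalizeRanks()].
#' @return `data.frame`: `gene_id`, `rho`, `p_adj`, plus the per-dataset
#'   ranks used.
#' @export
rraAggregate <- function(rank_matrix) {
  rank_matrix <- as.matrix(rank_matrix)
  k <- ncol(rank_matrix)
  rho <- apply(rank_matrix, 1, function(r) rraRho(sort(r), k))
  res <- data.frame(gene_id = rownames(rank_matrix), rho = rho,
                    p_adj = pmin(1, rho * k), stringsAsFactors = FALSE)
  res <- cbind(res, as.data.frame(rank_matrix))
  res <- res[order(res$p_adj, res$gene_id), ]
  rownames(res) <- NULL
  res
}

#' Rank-aggregate gene enrichment across datasets
#'
#' Convenience wrapper: takes [geneStats()] tables from two or more
#' datasets, ranks genes within each by the one-sided enrichment p value,
#' and aggregates with [rraAggregate()].
#'
#' @param gene_stat_list named list of [geneStats()] `data.frame`s.
#' @return sorted aggregation `data.frame` (see [rraAggregate()]).
#' @export
aggregateGeneRanks <- function(gene_stat_list) {
  stopIfNot(length(gene_stat_list) >= 2, "need at least two datasets")
  pl <- lapply(gene_stat_list, function(gs)
    setNames(gs$p_one_sided, gs$gene_id))
  rraAggregate(normalizeRanks(pl))
}
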