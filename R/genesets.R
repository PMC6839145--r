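#' Rank genes by differential-expression evidence
#'
#' Rank 1 is the most significant gene; ties share the average rank.
#'
#' @param de A `de_result` data.frame (or anything with `gene_id` and the
#'   ranking column).
#' @param by Column to rank on (default `p_value`, ascending).
#' @return Named numeric vector of ranks over the analysis universe.
#' @export
rank_genes <- function(de, by = "p_value") {
  v <- de[[by]]
  stopifnot(all(is.finite(v)))
  setNames(rank(v, ties.method = "average"), de$gene_id)
}

#' Competitive mean-rank gene-set test with a permutation null
#'
#' The observed statistic is the mean rank of the set members present in the
#' analysis universe; the null is built from `n_perm` uniformly random
#' subsets of the same size drawn without replacement from the universe.
#' Enrichment is one-sided towards significance (low mean rank):
#' `p = (1 + #\{T* <= T\}) / (n_perm + 1)`, so the smallest attainable p is
#' `1 / (n_perm + 1)`. With `two_sided = TRUE` the p-value is doubled on the
#' smaller tail (capped at 1).
#'
#' @param ranks Named rank vector from [rank_genes()].
#' @param gene_set Character vector of member gene ids.
#' @param n_perm Number of permutation subsets.
#' @param seed Optional seed for reproducible permutation draws.
#' @param two_sided Test both tails?
#' @return One-row data.frame: `n_in_universe`, `mean_rank`, `p_perm`,
#'   `two_sided`.
#' @export
mean_rank_test <- function(ranks, gene_set, n_perm = 10000, seed = NULL,
                           two_sided = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  members <- intersect(gene_set, names(ranks))
  k <- length(members)
  m <- length(ranks)
  if (k == 0L) {
    warning("gene set has no members in the universe")
    return(data.frame(n_in_universe = 0L, mean_rank = NA_real_,
                      p_perm = NA_real_, two_sided = two_sided))
  }
  obs <- mean(ranks[members])
  if (k == m) {
    warning("gene set covers the entire universe; test is non-informative")
  }
  rk <- unname(ranks)
  null_T <- vapply(seq_len(n_perm), function(i) mean(rk[sample.int(m, k)]), 0)
  p_low <- (1 + sum(null_T <= obs)) / (n_perm + 1)
  p <- if (two_sided) {
    p_high <- (1 + sum(null_T >= obs)) / (n_perm + 1)
    min(1, 2 * min(p_low, p_high))
  } else p_low
  data.frame(n_in_universe = k, mean_rank = obs, p_perm = p,
             two_sided = two_sided)
}

#' Test every set of a GMT collection
#'
#' Applies [mean_rank_test()] to each set with the same seed (identical sets
#' therefore get identical p-values). No cross-set multiplicity adjustment is
#' applied by default; an optional BH column can be added. Note the
#' permutation mean-rank machinery is also used for pathway collections, in
#' place of rotation-based testing; the `method` field of the result records
#' this.
#'
#' @param de A `de_result` (or ranked table accepted by [rank_genes()]).
#' @param gmt Named list of gene sets from [read_gmt()].
#' @param n_perm,seed,two_sided Passed to [mean_rank_test()].
#' @param adjust Add a BH-adjusted column?
#' @return Data.frame with one row per set, in collection order.
#' @export
run_collection <- function(de, gmt, n_perm = 10000, seed = NULL,
                           two_sided = FALSE, adjust = FALSE) {
  ranks <- rank_genes(de)
  if (length(gmt) == 0L) {
    return(data.frame(set_name = character(0), n_in_universe = integer(0),
                      mean_rank = numeric(0), p_perm = numeric(0)))
  }
  rows <- lapply(names(gmt), function(nm) {
    r <- mean_rank_test(ranks, gmt[[nm]], n_perm = n_perm, seed = seed,
                        two_sided = two_sided)
    cbind(data.frame(set_name = nm, stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    ok <- !is.na(out$p_perm)
    out$fdr <- NA_real_
    out$fdr[ok] <- benjamini_hochberg(out$p_perm[ok])
  }
  attr(out, "method") <- "permutation mean-rank (competitive)"
  out
}
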