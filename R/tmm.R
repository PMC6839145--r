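#' Trimmed mean of M-values normalisation factors
#'
#' TMM corrects compositional bias between libraries so that log fold changes
#' are minimised for the bulk of genes. For each sample against the reference,
#' genes expressed in both are scored by their log-ratio
#' `M = log2((y_s/L_s)/(y_r/L_r))` and average abundance
#' `A = 0.5 * log2((y_s/L_s) * (y_r/L_r))`; after trimming 30% from each tail
#' of M and 5% from each tail of A (by ranks), the factor is
#' `2^(sum(w M)/sum(w))` with delta-method precision weights
#' `w = (1/y_s - 1/L_s + 1/y_r - 1/L_r)^-1`. Factors are rescaled to
#' geometric mean 1. The reference defaults to the sample whose CPM 75th
#' percentile is closest to the mean of those percentiles.
#'
#' @param counts Gene x sample count matrix.
#' @param ref_sample Optional reference sample (name or column index).
#' @param logratio_trim,sum_trim Trim fractions for M and A.
#' @param lib_sizes Optional library sizes (defaults to column sums).
#' @return Named numeric vector of normalisation factors, one per sample,
#'   with geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05,
                        lib_sizes = NULL) {
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("zero library size")
  if (is.null(ref_sample)) {
    f75 <- apply(counts, 2L, quantile, probs = 0.75) / lib_sizes
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts)) else ref_sample
    if (is.na(ref) || ref < 1L || ref > ncol(counts)) stop("unknown reference sample")
  }
  f <- vapply(seq_len(ncol(counts)), function(s) {
    .tmm_pair(counts[, s], counts[, ref], lib_sizes[s], lib_sizes[ref],
              logratio_trim, sum_trim)
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

.tmm_pair <- function(y, yr, L, Lr, logratio_trim, sum_trim) {
  keep <- y > 0 & yr > 0
  if (!any(keep)) stop("no genes expressed in both sample and reference")
  y <- y[keep]; yr <- yr[keep]
  M <- log2((y / L) / (yr / Lr))
  A <- 0.5 * log2((y / L) * (yr / Lr))
  if (max(abs(M)) < 1e-6) return(1)
  w <- 1 / (1 / y - 1 / L + 1 / yr - 1 / Lr)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  use <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(use) || sum(w[use]) <= 0) return(1)
  2^(sum(w[use] * M[use]) / sum(w[use]))
}
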