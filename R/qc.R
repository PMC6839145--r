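#' Counts per million, optionally log2
#'
#' With `log = TRUE` the value is
#' `log2((y + prior) / (L + 2 * prior) * 1e6)`; the prior count (default 0.5,
#' with twice the prior added to the library size) keeps zero counts finite
#' and matches the fold-change conventions of the downstream DE stage.
#'
#' @param counts Gene x sample count matrix.
#' @param log Return log2 CPM?
#' @param prior Prior count added when `log = TRUE` (ignored with `log = FALSE`
#'   unless supplied explicitly).
#' @param lib_sizes Optional effective library sizes (defaults to column sums).
#' @return Matrix of (log) CPM values with the dimnames of `counts`.
#' @export
cpm <- function(counts, log = FALSE, prior = if (log) 0.5 else 0,
                lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("zero or negative library size")
  if (log) {
    t(log2(t(counts + prior) / (lib_sizes + 2 * prior) * 1e6))
  } else {
    t(t(counts + prior) / (lib_sizes + 2 * prior) * 1e6)
  }
}

#' Remove genes with insufficient expression
#'
#' Keeps a gene when its CPM is at least `min_cpm` in at least `min_samples`
#' samples; the sample set is unchanged. The filter is idempotent because CPM
#' is recomputed on the original library sizes supplied (column sums of the
#' input matrix are reused when `lib_sizes` is `NULL`, so filtering twice with
#' the same sizes keeps the same genes).
#'
#' @param counts Gene x sample count matrix.
#' @param min_cpm CPM threshold.
#' @param min_samples Minimum number of samples at or above the threshold.
#' @param lib_sizes Optional library sizes used for the CPM computation.
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_samples = 3,
                                  lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  x <- cpm(counts, log = FALSE, prior = 0, lib_sizes = lib_sizes)
  keep <- rowSums(x >= min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Sample-sample Pearson correlation structure
#'
#' Computes the full sample x sample Pearson correlation matrix over genes and
#' summarises it as the median correlation within complete twin pairs versus
#' the median over all unrelated sample pairs.
#'
#' @param lcm Log-CPM matrix (genes x samples).
#' @param sheet Sample sheet covering the columns of `lcm`.
#' @return List with `cor_matrix`, `median_within_pair_r`,
#'   `median_unrelated_r`.
#' @export
pairwise_correlation <- function(lcm, sheet) {
  if (ncol(lcm) < 2L) stop("at least two samples required")
  if (any(apply(lcm, 2L, sd) == 0)) stop("constant expression vector")
  cm <- cor(lcm)
  sheet <- sheet[match(colnames(lcm), sheet$sample_id), ]
  pair_of <- setNames(sheet$pair_id, sheet$sample_id)
  n <- ncol(cm)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  same_pair <- pair_of[colnames(cm)[idx[, 1L]]] == pair_of[colnames(cm)[idx[, 2L]]]
  list(cor_matrix = cm,
       median_within_pair_r = median(cm[idx][same_pair]),
       median_unrelated_r = median(cm[idx][!same_pair]))
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering on the Euclidean distance between logCPM columns.
#' Complete linkage by default (deterministic; ties broken by sample order as
#' in [stats::hclust()]).
#'
#' @param lcm Log-CPM matrix (genes x samples).
#' @param method Linkage method passed to [stats::hclust()].
#' @return An `hclust` tree with one leaf per sample.
#' @export
hierarchical_cluster <- function(lcm, method = "complete") {
  if (ncol(lcm) < 2L) stop("at least two samples required")
  hclust(dist(t(lcm)), method = method)
}

#' MDS on leading log fold changes
#'
#' For every pair of samples the distance is the root-mean-square of the
#' `top` largest absolute logCPM differences for that pair; classical
#' (Torgerson) MDS is then applied to the distance matrix.
#'
#' @param lcm Log-CPM matrix (genes x samples).
#' @param top Number of leading genes per sample pair.
#' @param k Number of output dimensions.
#' @return Samples x `k` coordinate matrix.
#' @export
mds_leading_logfc <- function(lcm, top = 500, k = 6) {
  n <- ncol(lcm)
  if (k >= n) stop("k must be smaller than the number of samples")
  top <- min(top, nrow(lcm))
  d <- matrix(0, n, n, dimnames = list(colnames(lcm), colnames(lcm)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dif <- sort(abs(lcm[, i] - lcm[, j]), decreasing = TRUE)[seq_len(top)]
      d[i, j] <- d[j, i] <- sqrt(mean(dif^2))
    }
  }
  coords <- cmdscale(as.dist(d), k = k)
  # pad with zero columns when the configuration is lower-dimensional
  if (ncol(coords) < k) {
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  colnames(coords) <- paste0("dim", seq_len(k))
  coords
}

#' Flag low-concordance outlier samples
#'
#' Advisory outlier call: a sample is flagged when its median correlation to
#' all other samples falls below `median - z_thresh * MAD` of that statistic
#' across samples (MAD with the usual 1.4826 consistency constant). Flagging
#' never removes samples by itself.
#'
#' @param qc Output of [pairwise_correlation()] (or any list holding a
#'   `cor_matrix`).
#' @param z_thresh Robust z-score threshold.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_outliers <- function(qc, z_thresh = 3) {
  cm <- qc$cor_matrix
  n <- ncol(cm)
  if (n <= 2L) {
    warning("outlier statistic undefined with fewer than three samples")
    return(character(0))
  }
  stat <- vapply(seq_len(n), function(i) median(cm[-i, i]), 0)
  cut <- median(stat) - z_thresh * mad(stat)
  colnames(cm)[stat < cut]
}

#' Full post-quantification QC report
#'
#' @param counts Filtered count matrix.
#' @param sheet Sample sheet.
#' @param top,k MDS parameters, see [mds_leading_logfc()].
#' @param z_thresh Outlier threshold, see [flag_outliers()].
#' @return List of class `qc_report` with the correlation summary, linkage
#'   tree, MDS coordinates and flagged outliers.
#' @export
qc_report <- function(counts, sheet, top = 500, k = 6, z_thresh = 3) {
  lcm <- cpm(counts, log = TRUE)
  qc <- pairwise_correlation(lcm, sheet)
  k <- min(k, ncol(lcm) - 1L)
  structure(list(
    median_within_pair_r = qc$median_within_pair_r,
    median_unrelated_r = qc$median_unrelated_r,
    cor_matrix = qc$cor_matrix,
    cluster = hierarchical_cluster(lcm),
    mds = mds_leading_logfc(lcm, top = top, k = k),
    outlier_samples = flag_outliers(qc, z_thresh = z_thresh)),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report: median within-pair r =", round(x$median_within_pair_r, 4),
      "; median unrelated r =", round(x$median_unrelated_r, 4), "\n")
  if (length(x$outlier_samples)) {
    cat("flagged outliers:", paste(x$outlier_samples, collapse = ", "), "\n")
  } else cat("no outliers flagged\n")
  invisible(x)
}
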