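#' Beta/M-value conversion
#'
#' `M = log2(Beta / (1 - Beta))`; the inverse is `Beta = 2^M / (2^M + 1)`.
#' M-values have distributional properties better suited to linear
#' modelling than the bounded Beta scale.
#'
#' @param beta Beta values strictly in (0, 1).
#' @return Matrix/vector of M-values.
#' @export
beta_to_m <- function(beta) {
  stopifnot(all(beta > 0 & beta < 1))
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m M-values.
#' @export
m_to_beta <- function(m) {
  b <- 2^m
  b / (b + 1)
}

#' Per-probe differential methylation by ordinary least squares
#'
#' Each probe's M-values are regressed on the paired design; the effect is
#' the `case` coefficient and the p-value a two-sided t-test on it with the
#' residual degrees of freedom. No variance moderation is applied. Probes
#' with identical values in all samples get effect 0, p = 1 and a
#' `degenerate` flag.
#'
#' @param m Probe x sample M-value matrix (columns matching the design rows).
#' @param X Design matrix from [build_design()].
#' @param manifest Probe manifest supplying `chrom` and `position`.
#' @return Data.frame `probe_id`, `chrom`, `position`, `effect`, `p_raw`,
#'   `p_slk` (NA until [slk_adjust()]), `degenerate`, ordered by
#'   chromosome and position.
#' @export
diff_methylation <- function(m, X, manifest) {
  test_coef <- attr(X, "test_coef")
  if (is.null(test_coef)) test_coef <- match("case", colnames(X))
  stopifnot(!is.na(test_coef))
  n <- nrow(X)
  df <- n - qr(X)$rank
  if (df < 1L) stop("no residual degrees of freedom")
  m <- m[, rownames(X), drop = FALSE]
  fit <- stats::lm.fit(X, t(m))
  coefs <- t(fit$coefficients)      # probes x p
  res <- t(fit$residuals)           # probes x n
  s2 <- rowSums(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * xtx_inv[test_coef, test_coef])
  effect <- coefs[, test_coef]
  tstat <- effect / se
  p <- 2 * pt(-abs(tstat), df = df)
  degen <- apply(m, 1L, var) == 0
  effect[degen] <- 0
  p[degen] <- 1
  out <- data.frame(probe_id = rownames(m), stringsAsFactors = FALSE)
  idx <- match(out$probe_id, manifest$probe_id)
  out$chrom <- manifest$chrom[idx]
  out$position <- manifest$position[idx]
  out$effect <- effect
  out$p_raw <- p
  out$p_slk <- NA_real_
  out$degenerate <- degen
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance-binned autocorrelation of methylation test statistics
#'
#' Raw p-values are transformed to one-sided z-scores `z = qnorm(1 - p)`; for
#' each distance bin `(0, bw], (bw, 2 bw], ...` up to `max_dist` the Pearson
#' correlation is computed over all same-chromosome probe pairs whose
#' separation falls in the bin. Bins with fewer than `min_pairs` pairs
#' inherit the nearest populated bin's value, and negative estimates are
#' floored at 0 (the spatial combination requires a positive semi-definite
#' working correlation).
#'
#' @param probes Probe result table from [diff_methylation()], position
#'   sorted.
#' @param max_dist Maximum pair separation (bp).
#' @param bin_width Bin width (bp).
#' @param min_pairs Minimum pairs per bin before borrowing.
#' @return Data.frame of class `acf_table`: `dist_upper`, `correlation`,
#'   `n_pairs`.
#' @export
estimate_acf <- function(probes, max_dist = 2000, bin_width = 500,
                         min_pairs = 10L) {
  z <- .p_to_z(probes$p_raw)
  n_bins <- ceiling(max_dist / bin_width)
  pairs_a <- vector("list", n_bins)
  pairs_b <- vector("list", n_bins)
  any_pair <- FALSE
  for (ch in unique(probes$chrom)) {
    sel <- which(probes$chrom == ch)
    if (length(sel) < 2L) next
    pos <- probes$position[sel]
    o <- order(pos); sel <- sel[o]; pos <- pos[o]
    for (i in seq_len(length(sel) - 1L)) {
      j <- i + 1L
      while (j <= length(sel) && pos[j] - pos[i] <= max_dist) {
        d <- pos[j] - pos[i]
        b <- max(1L, ceiling(d / bin_width))
        pairs_a[[b]] <- c(pairs_a[[b]], z[sel[i]])
        pairs_b[[b]] <- c(pairs_b[[b]], z[sel[j]])
        any_pair <- TRUE
        j <- j + 1L
      }
    }
  }
  if (!any_pair) stop("fewer than two probes within max_dist on every chromosome")
  n_pairs <- vapply(pairs_a, length, 1L)
  corr <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    if (n_pairs[b] >= min_pairs &&
        sd(pairs_a[[b]]) > 0 && sd(pairs_b[[b]]) > 0) {
      corr[b] <- cor(pairs_a[[b]], pairs_b[[b]])
    } else if (n_pairs[b] >= 2L && isTRUE(all.equal(pairs_a[[b]], pairs_b[[b]]))) {
      corr[b] <- 1  # identical duplicated probes: perfect correlation
    }
  }
  if (all(is.na(corr))) corr[] <- 0
  # borrow from the nearest populated bin
  for (b in which(is.na(corr))) {
    ok <- which(!is.na(corr))
    corr[b] <- corr[ok[which.min(abs(ok - b))]]
  }
  corr <- pmax(corr, 0)
  structure(data.frame(dist_upper = bin_width * seq_len(n_bins),
                       correlation = corr, n_pairs = n_pairs),
            class = c("acf_table", "data.frame"))
}

.p_to_z <- function(p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  qnorm(1 - p)
}

# working correlation at distance d (d = 0 means co-located or the diagonal)
.acf_lookup <- function(acf, d) {
  out <- numeric(length(d))
  out[d == 0] <- 1
  pos <- d > 0
  if (any(pos)) {
    b <- pmin(ceiling(d[pos] / (acf$dist_upper[1L])), nrow(acf))
    out[pos] <- acf$correlation[b]
  }
  out
}

#' Stouffer-Liptak spatial adjustment of probe p-values
#'
#' For each probe the z-scores of all same-chromosome probes within
#' `dist` bp (including itself) are combined as
#' `z_comb = sum(z_j) / sqrt(sum_jk sigma_jk)` with `sigma_jk` taken from the
#' distance-binned autocorrelation (1 on the diagonal);
#' `p_slk = 1 - pnorm(z_comb)`. An isolated probe keeps its raw p-value.
#'
#' @param probes Probe result table from [diff_methylation()].
#' @param acf An `acf_table` from [estimate_acf()].
#' @param dist Neighbourhood half-width in bp.
#' @return The probe table with `p_slk` filled.
#' @export
slk_adjust <- function(probes, acf, dist = 2000) {
  z <- .p_to_z(probes$p_raw)
  p_slk <- numeric(nrow(probes))
  for (ch in unique(probes$chrom)) {
    sel <- which(probes$chrom == ch)
    pos <- probes$position[sel]
    o <- order(pos); sel <- sel[o]; pos <- pos[o]
    for (ii in seq_along(sel)) {
      nb <- which(abs(pos - pos[ii]) <= dist)
      if (length(nb) == 1L) {
        p_slk[sel[ii]] <- probes$p_raw[sel[ii]]
        next
      }
      zz <- z[sel[nb]]
      dmat <- abs(outer(pos[nb], pos[nb], "-"))
      sig <- matrix(.acf_lookup(acf, as.vector(dmat)), length(nb))
      diag(sig) <- 1
      denom <- sum(sig)
      p_slk[sel[ii]] <- pnorm(sum(zz) / sqrt(denom), lower.tail = FALSE)
    }
  }
  probes$p_slk <- p_slk
  probes
}

#' Gene-level methylation p-value
#'
#' Summarises probe-level spatially adjusted p-values per gene by the minimum;
#' no multiplicity adjustment is applied (the value is a ranking statistic).
#' Genes without probes are absent from the output.
#'
#' @param probes Probe table with `p_slk` filled.
#' @param manifest Probe manifest mapping probes to genes.
#' @return Data.frame `gene_id`, `p_meth_gene`.
#' @export
gene_min_p <- function(probes, manifest) {
  gid <- manifest$gene_id[match(probes$probe_id, manifest$probe_id)]
  v <- tapply(probes$p_slk, gid, min)
  data.frame(gene_id = names(v), p_meth_gene = as.numeric(v),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical Brown combination of two dependent p-values
#'
#' Fisher's statistic `Xf = -2 (ln p_expr + ln p_meth)` is referred to a
#' scaled chi-square whose moments account for the dependence between the two
#' assays, estimated from the per-sample data vectors: each vector is
#' transformed to evidence scores `w(s) = -2 ln(rank(v_s)/n)` (maximum-rank
#' ties, so the largest value maps to w = 0), and `c = cov(w_x, w_y)` enters
#' the Brown moments `E = 4`, `Var = 8 + 2c`, giving `df = 2 E^2 / Var` and
#' `scale = Var / (2 E)`. With `c = 0` the combination reduces exactly to
#' Fisher's method.
#'
#' @param p_expr,p_meth P-values in (0, 1).
#' @param x,y Per-sample data vectors for the gene (same samples, at least
#'   three): expression CPM and methylation summary respectively.
#' @return List `p_combined`, `df`, `scale`, `cov_w`.
#' @export
empirical_brown <- function(p_expr, p_meth, x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            p_expr > 0, p_expr <= 1, p_meth > 0, p_meth <= 1)
  n <- length(x)
  if (var(x) == 0 || var(y) == 0) {
    warning("constant data vector; falling back to independence (Fisher)")
    cw <- 0
  } else {
    wx <- -2 * log(rank(x, ties.method = "max") / n)
    wy <- -2 * log(rank(y, ties.method = "max") / n)
    cw <- cov(wx, wy)
  }
  E <- 4
  V <- 8 + 2 * cw
  if (V <= 0) { cw <- 0; V <- 8 }
  df <- 2 * E^2 / V
  scale <- V / (2 * E)
  Xf <- -2 * (log(p_expr) + log(p_meth))
  list(p_combined = pchisq(Xf / scale, df = df, lower.tail = FALSE),
       df = df, scale = scale, cov_w = cw)
}

#' Spearman correlation between gene expression and methylation
#'
#' Pearson correlation of ranks with average-rank ties.
#'
#' @param x Per-sample CPM vector for the gene.
#' @param y Per-sample median-Beta vector for the gene.
#' @return Spearman's rho.
#' @export
spearman_gene <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (var(x) == 0 || var(y) == 0) stop("constant vector")
  cor(x, y, method = "spearman")
}

#' Run the methylation arm of the integrative analysis
#'
#' Converts Beta to M-values, fits the per-probe paired linear model,
#' estimates the spatial autocorrelation and applies the Stouffer-Liptak
#' adjustment.
#'
#' @param meth A `methylation_set`.
#' @param sheet Sample sheet.
#' @param analysis Design selection, see [build_design()].
#' @param dist Spatial adjustment distance (bp).
#' @param bin_width ACF bin width (bp).
#' @return List with `probes` (adjusted probe table), `acf` and `design`.
#' @export
run_methylation <- function(meth, sheet,
                            analysis = c("discordant_group", "case_control"),
                            dist = 2000, bin_width = 500) {
  analysis <- match.arg(analysis)
  sheet_m <- sheet[sheet$sample_id %in% colnames(meth$beta), , drop = FALSE]
  X <- build_design(sheet_m, analysis)
  m <- beta_to_m(meth$beta)
  probes <- diff_methylation(m, X, meth$manifest)
  acf <- estimate_acf(probes, max_dist = dist, bin_width = bin_width)
  probes <- slk_adjust(probes, acf, dist = dist)
  list(probes = probes, acf = acf, design = X)
}

#' Combine expression and methylation evidence per gene
#'
#' For every gene measured in both assays: the expression LRT p-value and the
#' gene-level minimum spatially adjusted methylation p-value are combined by
#' [empirical_brown()] using the gene's per-sample normalised CPM and median
#' Beta vectors (over the shared samples), and Spearman's rho between those
#' vectors is reported. Genes are sorted by combined p (ties by gene id).
#'
#' @param de A `de_result`.
#' @param probes Adjusted probe table with `p_slk` (from [run_methylation()]
#'   or [slk_adjust()]).
#' @param meth The `methylation_set` (supplies Beta values and manifest).
#' @param counts Count matrix for the expression arm.
#' @param top_k Size of the highlighted top slice (default 20).
#' @param norm_factors Optional TMM factors for `counts`.
#' @return Data.frame of class `integration_result`: `gene_id`, `p_expr`,
#'   `p_meth_gene`, `cov_w`, `df_brown`, `scale_brown`, `p_combined`,
#'   `spearman_rho`, `rank`; the top slice is in the `top` attribute.
#' @export
integrate_omics <- function(de, probes, meth, counts, top_k = 20,
                            norm_factors = NULL) {
  shared <- intersect(colnames(counts), colnames(meth$beta))
  if (length(shared) < 3L) stop("fewer than three samples shared between assays")
  gmp <- gene_min_p(probes, meth$manifest)
  genes <- sort(intersect(de$gene_id, gmp$gene_id))
  if (!length(genes)) stop("no genes measured in both assays")
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  nf <- norm_factors[colnames(counts)]
  if (anyNA(nf)) {
    warning("norm_factors do not cover every sample of `counts`; recomputing TMM")
    nf <- tmm_factors(counts)
  }
  x_all <- cpm(counts[, shared, drop = FALSE], log = FALSE, prior = 0,
               lib_sizes = (colSums(counts) * nf)[shared])
  p_expr <- setNames(de$p_value, de$gene_id)
  p_meth <- setNames(gmp$p_meth_gene, gmp$gene_id)
  probe_gene <- meth$manifest$gene_id
  rows <- lapply(genes, function(g) {
    pr <- meth$manifest$probe_id[probe_gene == g]
    yb <- meth$beta[pr, shared, drop = FALSE]
    yv <- apply(yb, 2L, median)
    xv <- x_all[g, ]
    eb <- suppressWarnings(
      empirical_brown(min(p_expr[[g]], 1), min(p_meth[[g]], 1), xv, yv))
    rho <- if (var(xv) == 0 || var(yv) == 0) NA_real_ else spearman_gene(xv, yv)
    data.frame(gene_id = g, p_expr = p_expr[[g]], p_meth_gene = p_meth[[g]],
               cov_w = eb$cov_w, df_brown = eb$df, scale_brown = eb$scale,
               p_combined = eb$p_combined, spearman_rho = rho,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_combined, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("integration_result", "data.frame"),
            top = utils::head(out, top_k))
}

#' @export
print.integration_result <- function(x, ...) {
  cat("integration_result:", nrow(x), "genes in both assays; top slice:\n")
  print.data.frame(attr(x, "top"))
  invisible(x)
}
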