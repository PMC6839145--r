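#' Estimate surrogate variables from residual expression structure
#'
#' Two-step estimator: the logCPM matrix is residualised against the design
#' (`R = Y (I - X (X'X)^-1 X')`), and the number of informative components is
#' chosen by a Buja-Eyuboglu permutation test — component k is kept while its
#' singular-value variance fraction exceeds the `1 - alpha` quantile of the
#' same fraction under row-wise permutations of `R`. Surrogate variables are
#' the corresponding right singular vectors, which are orthonormal and lie in
#' the orthogonal complement of the design column space by construction.
#'
#' @param lcm LogCPM matrix (genes x samples).
#' @param X Design matrix (samples x coefficients).
#' @param n_perm Number of row-wise permutations.
#' @param alpha Per-component significance level.
#' @param seed Optional seed for the permutations.
#' @return List of class `surrogate_variables`: `n_sv`, `sv` (samples x
#'   `n_sv`), `eigen_fractions` (observed variance fractions).
#' @export
estimate_svs <- function(lcm, X, n_perm = 100, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(lcm)
  stopifnot(nrow(X) == n)
  if (n < ncol(X) + 1L) stop("need more samples than design coefficients")
  H <- X %*% chol2inv(chol(crossprod(X))) %*% t(X)
  R <- lcm - lcm %*% H

  frac_of <- function(M) {
    d2 <- svd(M, nu = 0, nv = 0)$d^2
    d2 / sum(d2)
  }
  obs <- frac_of(R)
  k_max <- length(obs)
  perm_frac <- matrix(0, n_perm, k_max)
  G <- nrow(R)
  for (b in seq_len(n_perm)) {
    Rp <- R
    for (g in seq_len(G)) Rp[g, ] <- Rp[g, sample.int(n)]
    # permuted rows leave the design space; re-residualise to compare like
    # with like
    Rp <- Rp - Rp %*% H
    perm_frac[b, ] <- frac_of(Rp)
  }
  thresh <- apply(perm_frac, 2L, quantile, probs = 1 - alpha)
  keep <- obs > thresh
  n_sv <- if (keep[1L]) which.min(c(keep, FALSE)) - 1L else 0L  # leading run
  sv <- if (n_sv > 0L) svd(R, nu = 0, nv = n_sv)$v else
    matrix(0, n, 0L)
  rownames(sv) <- colnames(lcm)
  structure(list(n_sv = as.integer(n_sv), sv = sv, eigen_fractions = obs),
            class = "surrogate_variables")
}

#' Append surrogate variables to a design matrix
#'
#' SV columns are appended after the existing coefficients; the tested
#' (`case`) coefficient index is preserved. An error is raised if the
#' augmented matrix is rank deficient.
#'
#' @param X Design matrix from [build_design()].
#' @param svs A `surrogate_variables` object (or a numeric matrix of
#'   covariate columns).
#' @return The augmented design matrix.
#' @export
augment_design <- function(X, svs) {
  sv <- if (inherits(svs, "surrogate_variables")) svs$sv else as.matrix(svs)
  if (ncol(sv) == 0L) return(X)
  colnames(sv) <- if (is.null(colnames(sv))) paste0("sv", seq_len(ncol(sv))) else colnames(sv)
  out <- cbind(X, sv[rownames(X), , drop = FALSE])
  if (qr(out)$rank < ncol(out)) stop("augmented design is rank deficient")
  attr(out, "test_coef") <- attr(X, "test_coef")
  attr(out, "samples") <- attr(X, "samples")
  attr(out, "sheet") <- attr(X, "sheet")
  out
}

#' @export
print.surrogate_variables <- function(x, ...) {
  cat("surrogate_variables: n_sv =", x$n_sv, "\n")
  invisible(x)
}
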