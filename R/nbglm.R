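#' Negative-binomial log-likelihood
#'
#' `sum(lgamma(y + 1/phi) - lgamma(1/phi) - lgamma(y + 1) +
#'  y * log(phi*mu/(1 + phi*mu)) - (1/phi) * log(1 + phi*mu))`,
#' with terms involving `y` skipped for zero counts so the `mu -> 0` limit is
#' exact.
#'
#' @param y Non-negative counts.
#' @param mu Positive means.
#' @param phi Dispersion (> 0); variance is `mu + phi * mu^2`.
#' @return Scalar log-likelihood.
#' @export
nb_loglik <- function(y, mu, phi) {
  inv <- 1 / phi
  mu <- pmin(pmax(mu, 1e-10), 1e12)
  ll <- sum(-inv * log1p(phi * mu))
  pos <- y > 0
  if (any(pos)) {
    yp <- y[pos]; mp <- mu[pos]
    ll <- ll + sum(lgamma(yp + inv) - lgamma(inv) - lgamma(yp + 1) +
                     yp * (log(phi * mp) - log1p(phi * mp)))
  }
  ll
}

#' Fit a negative-binomial GLM for one gene
#'
#' Maximises the NB log-likelihood for `log mu = X beta + offsets` at fixed
#' dispersion, by iteratively reweighted least squares with step halving.
#' Convergence when the log-likelihood changes by less than `tol` (default
#' 1e-8) or after 100 iterations; non-convergence is reported via the
#' `converged` flag, never by dropping the gene.
#'
#' @param y Count vector for one gene.
#' @param X Design matrix (samples x coefficients), full rank.
#' @param offsets Natural-log effective library sizes.
#' @param phi Dispersion (> 0).
#' @return List with `coefficients` (named), `loglik`, `fitted` and
#'   `converged`.
#' @export
fit_nb_glm <- function(y, X, offsets, phi) {
  stopifnot(phi > 0, length(y) == nrow(X), length(offsets) == nrow(X))
  fit <- .cxx_nb_fit(matrix(as.numeric(y), nrow = 1L), X,
                     as.numeric(offsets), phi)
  beta <- drop(fit$coefficients)
  names(beta) <- colnames(X)
  list(coefficients = beta,
       loglik = fit$loglik[1L],
       fitted = drop(exp(X %*% beta + offsets)),
       converged = fit$converged[1L])
}

# Fit all genes of a count matrix at once (rows = genes); phi recycled.
.nb_fit_matrix <- function(counts, X, offsets, phi) {
  phi <- rep_len(phi, nrow(counts))
  fit <- .cxx_nb_fit(`storage.mode<-`(counts, "double"), X,
                     as.numeric(offsets), phi)
  dimnames(fit$coefficients) <- list(rownames(counts), colnames(X))
  fit
}
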