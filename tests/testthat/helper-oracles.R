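# Independent brute-force oracles used to validate the optimised
# implementations. These deliberately share no code with the package
# internals.

# NB log-likelihood, direct transcription of the density
oracle_nb_ll <- function(y, mu, phi) {
  inv <- 1 / phi
  sum(lgamma(y + inv) - lgamma(inv) - lgamma(y + 1) +
        y * log(phi * mu / (1 + phi * mu)) - inv * log(1 + phi * mu))
}

# Grid maximisation of the NB log-likelihood for a design with one or two
# columns (intercept, optionally a covariate). Coarse-to-fine refinement down
# to `final_step`.
oracle_nb_grid_fit <- function(y, x = NULL, offsets, phi,
                               final_step = 1e-5) {
  two <- !is.null(x)
  ll_at <- function(b0, b1 = 0) {
    eta <- b0 + (if (two) b1 * x else 0) + offsets
    oracle_nb_ll(y, pmax(exp(eta), 1e-12), phi)
  }
  c0 <- log(sum(y) / sum(exp(offsets)) + 1e-8)
  c1 <- 0
  half0 <- 3; half1 <- 3
  step <- 0.05
  repeat {
    g0 <- seq(c0 - half0, c0 + half0, by = step)
    g1 <- if (two) seq(c1 - half1, c1 + half1, by = step) else 0
    best <- -Inf
    for (b1 in g1) {
      lls <- vapply(g0, ll_at, 0, b1 = b1)
      i <- which.max(lls)
      if (lls[i] > best) { best <- lls[i]; c0 <- g0[i]; c1 <- b1 }
    }
    if (step <= final_step) break
    half0 <- half1 <- 2.5 * step
    step <- max(step / 50, final_step)
  }
  list(b0 = c0, b1 = c1, loglik = ll_at(c0, c1))
}

# Literal re-implementation of the doubly trimmed weighted mean of M-values
# for one sample against a reference (plain loops, no shortcuts)
oracle_tmm_pair <- function(y, yr, L, Lr, trimM = 0.3, trimA = 0.05) {
  keep <- which(y > 0 & yr > 0)
  M <- A <- w <- numeric(0)
  for (g in keep) {
    M <- c(M, log2((y[g] / L) / (yr[g] / Lr)))
    A <- c(A, 0.5 * log2((y[g] / L) * (yr[g] / Lr)))
    w <- c(w, 1 / (1 / y[g] - 1 / L + 1 / yr[g] - 1 / Lr))
  }
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  num <- 0; den <- 0
  for (g in seq_len(n)) {
    if (rM[g] >= loM && rM[g] <= hiM && rA[g] >= loA && rA[g] <= hiA) {
      num <- num + w[g] * M[g]
      den <- den + w[g]
    }
  }
  2^(num / den)
}

# Supremum of |F_a - F_b| evaluated on a fine grid over the pooled support
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  grid <- sort(c(pts, pts - 1e-9, pts + 1e-9))
  Fa <- ecdf(a); Fb <- ecdf(b)
  max(abs(Fa(grid) - Fb(grid)))
}

# Evidence-score transform of the empirical Brown combination, written out
# by hand
oracle_brown_w <- function(v) {
  n <- length(v)
  r <- rank(v, ties.method = "max")
  -2 * log(r / n)
}
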