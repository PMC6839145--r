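sva_setup <- function(G = 400, seed = 91, batch_shift = 0) {
  set.seed(seed)
  sheet <- toy_sheet(5)
  X <- build_design(sheet, "discordant_group")
  n <- nrow(X)
  lcm <- matrix(rnorm(G * n, mean = 6, sd = 1), G, n,
                dimnames = list(sprintf("g%04d", 1:G), rownames(X)))
  # plant the batch in the orthogonal complement of the design, so the pair
  # and case terms cannot absorb it
  raw <- rep(c(0, 1), each = n / 2)
  batch <- raw - X %*% solve(crossprod(X), crossprod(X, raw))
  batch <- as.vector(batch) / sqrt(sum(batch^2)) * sqrt(n) / 2
  if (batch_shift != 0) {
    hit <- seq_len(round(0.3 * G))
    lcm[hit, ] <- lcm[hit, ] + batch_shift * matrix(batch, length(hit), n, byrow = TRUE)
  }
  list(lcm = lcm, X = X, batch = batch)
}

test_that("pure noise yields zero surrogate variables in most seeded runs", {
  hits <- vapply(1:10, function(s) {
    d <- sva_setup(seed = 90 + s)
    estimate_svs(d$lcm, d$X, n_perm = 60, seed = 1000 + s)$n_sv
  }, 0L)
  expect_gte(mean(hits == 0L), 0.9)
})

test_that("a planted orthogonal batch is recovered as the first SV", {
  d <- sva_setup(seed = 95, batch_shift = 1)
  svs <- estimate_svs(d$lcm, d$X, n_perm = 100, seed = 2)
  expect_gte(svs$n_sv, 1L)
  expect_gt(abs(cor(svs$sv[, 1], d$batch)), 0.8)
})

test_that("surrogate variables are orthonormal and orthogonal to the design", {
  d <- sva_setup(seed = 96, batch_shift = 1.5)
  svs <- estimate_svs(d$lcm, d$X, n_perm = 100, seed = 3)
  expect_gte(svs$n_sv, 1L)
  gram <- crossprod(svs$sv)
  expect_equal(gram, diag(ncol(svs$sv)), tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(crossprod(d$X, svs$sv))), 1e-8)
})

test_that("design augmentation preserves the tested coefficient and adds rank", {
  d <- sva_setup(seed = 97, batch_shift = 1.5)
  svs <- estimate_svs(d$lcm, d$X, n_perm = 100, seed = 4)
  X2 <- augment_design(d$X, svs)
  expect_equal(qr(X2)$rank, qr(d$X)$rank + svs$n_sv)
  expect_equal(attr(X2, "test_coef"), attr(d$X, "test_coef"))

  none <- structure(list(n_sv = 0L, sv = matrix(0, nrow(d$X), 0)),
                    class = "surrogate_variables")
  expect_identical(augment_design(d$X, none), d$X)
})

test_that("estimation is deterministic given the seed", {
  d <- sva_setup(seed = 98, batch_shift = 1)
  a <- estimate_svs(d$lcm, d$X, n_perm = 50, seed = 9)
  b <- estimate_svs(d$lcm, d$X, n_perm = 50, seed = 9)
  expect_identical(a, b)
})

test_that("DE recovery is robust to surrogate-variable adjustment", {
  co <- simulate_cohort(sim_config(n_genes = 800, n_de_genes = 40, seed = 99))
  f <- filter_low_expression(co$counts)
  # plant a batch orthogonal to case on 30% of genes
  X0 <- suppressWarnings(build_design(co$sheet, "discordant_group"))
  samples <- attr(X0, "samples")
  batch <- rep(c(0, 1), length.out = length(samples))
  fb <- f
  hit <- seq_len(round(0.3 * nrow(f)))
  fb[hit, samples] <- round(sweep(fb[hit, samples, drop = FALSE], 2, 2^batch, `*`))
  storage.mode(fb) <- "integer"

  lcm <- suppressWarnings(cpm(fb[, samples], log = TRUE))
  svs <- estimate_svs(lcm, X0, n_perm = 60, seed = 12)
  de_plain <- suppressWarnings(lrt_case(f, co$sheet, "discordant_group"))
  de_sv <- suppressWarnings(lrt_case(fb, co$sheet, "discordant_group",
                                     extra_covariates = svs$sv))
  tr <- co$truth$de_genes$gene_id
  hit_plain <- mean(de_plain$fdr[match(tr, de_plain$gene_id)] < 0.1, na.rm = TRUE)
  hit_sv <- mean(de_sv$fdr[match(tr, de_sv$gene_id)] < 0.1, na.rm = TRUE)
  expect_gte(hit_sv, hit_plain - 0.10)
})
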