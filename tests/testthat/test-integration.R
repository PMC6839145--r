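test_that("Beta/M conversion is exact at reference points and bijective", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  set.seed(81)
  m <- matrix(rnorm(100, 0, 2), 10, 10)
  expect_equal(beta_to_m(m_to_beta(m)), m, tolerance = 1e-12)
  expect_error(beta_to_m(1.2))
})

test_that("per-probe OLS recovers planted effects and degenerates safely", {
  sheet <- toy_sheet(5)
  X <- build_design(sheet, "discordant_group")
  set.seed(82)
  n <- nrow(X)
  n_probe <- 100
  delta <- 2
  m <- matrix(rnorm(n_probe * n, sd = 0.5), n_probe, n,
              dimnames = list(sprintf("p%03d", 1:n_probe), rownames(X)))
  m <- m + delta * matrix(X[, "case"], n_probe, n, byrow = TRUE)
  manifest <- data.frame(chrom = "chr1", position = 1000 * seq_len(n_probe),
                         probe_id = rownames(m), gene_id = "g",
                         stringsAsFactors = FALSE)
  res <- diff_methylation(m, X, manifest)
  expect_lt(abs(mean(res$effect) - delta), 0.5)

  # constant probe
  m2 <- rbind(m, const = rep(0.3, n))
  manifest2 <- rbind(manifest, data.frame(chrom = "chr1", position = 999999,
                                          probe_id = "const", gene_id = "g"))
  res2 <- diff_methylation(m2, X, manifest2)
  row <- res2[res2$probe_id == "const", ]
  expect_equal(row$p_raw, 1)
  expect_equal(row$effect, 0)
  expect_true(row$degenerate)
})

test_that("null probe p-values are uniform", {
  sheet <- toy_sheet(5)
  X <- build_design(sheet, "discordant_group")
  set.seed(83)
  m <- matrix(rnorm(2000 * nrow(X), sd = 0.5), 2000, nrow(X),
              dimnames = list(sprintf("p%04d", 1:2000), rownames(X)))
  manifest <- data.frame(chrom = "chr1", position = 1000 * 1:2000,
                         probe_id = rownames(m), gene_id = "g")
  res <- diff_methylation(m, X, manifest)
  expect_gt(ks.test(res$p_raw, "punif")$p.value, 0.01)
})

test_that("ACF estimation: null is near zero, AR(1) decays, identical pairs give 1", {
  # null: i.i.d. p-values on a dense chromosome
  set.seed(84)
  n <- 3000
  probes <- data.frame(probe_id = sprintf("p%04d", 1:n), chrom = "chr1",
                       position = 100 * (1:n), p_raw = runif(n),
                       stringsAsFactors = FALSE)
  acf0 <- estimate_acf(probes, max_dist = 2000, bin_width = 500)
  expect_true(all(acf0$correlation < 0.05))  # floored at 0 from below

  # AR(1)-correlated z-scores: correlations decrease with distance
  z <- numeric(n); z[1] <- rnorm(1)
  for (i in 2:n) z[i] <- 0.6 * z[i - 1] + sqrt(1 - 0.36) * rnorm(1)
  probes_ar <- probes
  probes_ar$p_raw <- 1 - pnorm(z)
  probes_ar$position <- 500 * (1:n)
  acf_ar <- estimate_acf(probes_ar, max_dist = 2000, bin_width = 500)
  expect_true(all(diff(acf_ar$correlation) < 0))
  expect_gt(acf_ar$correlation[1], 0.4)

  # duplicated identical probes at 1 bp
  dup <- data.frame(probe_id = sprintf("d%02d", 1:40), chrom = "chr2",
                    position = rep(10000 * (1:20), each = 2) + c(0, 1),
                    p_raw = rep(runif(20), each = 2), stringsAsFactors = FALSE)
  acf_dup <- estimate_acf(dup, max_dist = 2000, bin_width = 500)
  expect_equal(acf_dup$correlation[1], 1)
})

test_that("Stouffer-Liptak adjustment has the stated analytic limits", {
  acf0 <- structure(data.frame(dist_upper = c(500, 1000, 1500, 2000),
                               correlation = rep(0, 4), n_pairs = 100L),
                    class = c("acf_table", "data.frame"))
  # isolated probe: identity
  iso <- data.frame(probe_id = "a", chrom = "chr1", position = 100,
                    p_raw = 0.037, p_slk = NA_real_, stringsAsFactors = FALSE)
  expect_equal(slk_adjust(iso, acf0)$p_slk, 0.037, tolerance = 1e-12)

  # two co-located probes with identical z and correlation 1: identity
  acf1 <- acf0; acf1$correlation <- rep(1, 4)
  two <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                    position = c(100, 100), p_raw = c(0.05, 0.05),
                    p_slk = NA_real_, stringsAsFactors = FALSE)
  expect_equal(slk_adjust(two, acf1)$p_slk, c(0.05, 0.05), tolerance = 1e-10)

  # k = 4 independent equal-z neighbours: z_comb = sqrt(k) z
  z1 <- 1
  four <- data.frame(probe_id = letters[1:4], chrom = "chr1",
                     position = c(0, 500, 1000, 1500),
                     p_raw = rep(1 - pnorm(z1), 4), p_slk = NA_real_,
                     stringsAsFactors = FALSE)
  out <- slk_adjust(four, acf0, dist = 2000)
  expect_equal(out$p_slk, rep(1 - pnorm(2), 4), tolerance = 1e-10)
})

test_that("gene-level summary takes the minimum adjusted p", {
  probes <- data.frame(probe_id = c("a", "b", "c", "d"),
                       p_slk = c(0.5, 0.01, 0.2, 0.9))
  manifest <- data.frame(probe_id = c("a", "b", "c", "d"),
                         gene_id = c("g1", "g1", "g1", "g2"))
  gp <- gene_min_p(probes, manifest)
  expect_equal(gp$p_meth_gene[gp$gene_id == "g1"], 0.01)
  expect_equal(gp$p_meth_gene[gp$gene_id == "g2"], 0.9)
  expect_true(all(gp$p_meth_gene <= tapply(probes$p_slk, manifest$gene_id, min)))
})

test_that("empirical Brown reduces to Fisher at zero covariance and is less
           anti-conservative under perfect dependence", {
  set.seed(85)
  x <- rnorm(20)
  # constant y: falls back to Fisher with a warning
  expect_warning(eb0 <- empirical_brown(0.03, 0.2, x, rep(1, 20)), "constant")
  fisher_p <- pchisq(-2 * (log(0.03) + log(0.2)), df = 4, lower.tail = FALSE)
  expect_equal(eb0$p_combined, fisher_p, tolerance = 1e-12)
  expect_equal(eb0$df, 4)
  expect_equal(eb0$scale, 1)

  # boundary: both p = 1
  expect_warning(eb1 <- empirical_brown(1, 1, x, rep(1, 20)))
  expect_equal(eb1$p_combined, 1)

  # perfect dependence: y a strictly monotone transform of x
  y <- exp(2 * x)
  eb2 <- empirical_brown(0.01, 0.01, x, y)
  wx <- oracle_brown_w(x)
  expect_equal(eb2$cov_w, var(wx), tolerance = 1e-10)
  fisher2 <- pchisq(-2 * 2 * log(0.01), df = 4, lower.tail = FALSE)
  expect_gt(eb2$p_combined, fisher2)
})

test_that("Spearman correlation handles ties and hand-computed cases", {
  expect_equal(spearman_gene(1:5, 1:5), 1)
  expect_equal(spearman_gene(1:5, 5:1), -1)
  expect_equal(spearman_gene(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4)), 0.8)
  expect_error(spearman_gene(1:5, rep(1, 5)), "constant")
})

test_that("integration keeps only genes in both assays and ranks linked genes high", {
  co <- simulate_cohort(sim_config(n_genes = 600, n_de_genes = 30,
                                   n_linked_genes = 6, seed = 86))
  f <- filter_low_expression(co$counts)
  de <- suppressWarnings(lrt_case(f, co$sheet, "discordant_group"))
  suppressWarnings(marm <- run_methylation(co$meth, co$sheet, "discordant_group"))
  integ <- integrate_omics(de, marm$probes, co$meth, f)
  meas_meth <- unique(co$meth$manifest$gene_id)
  expect_true(all(integ$gene_id %in% intersect(de$gene_id, meas_meth)))
  # a gene measured in expression only is absent
  only_expr <- setdiff(de$gene_id, meas_meth)[1]
  expect_false(only_expr %in% integ$gene_id)
  # linked genes (true effects in both assays) rank above the others
  linked <- intersect(co$truth$linked_genes, integ$gene_id)
  med_linked <- median(integ$rank[match(linked, integ$gene_id)])
  med_other <- median(integ$rank[!(integ$gene_id %in% linked)])
  expect_lt(med_linked, med_other)
  # top_k larger than the table returns everything
  integ2 <- suppressWarnings(integrate_omics(de, marm$probes, co$meth, f, top_k = 1e6))
  expect_equal(nrow(attr(integ2, "top")), nrow(integ2))
})
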