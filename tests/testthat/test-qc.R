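test_that("cpm matches its formula, is exact without prior, and is scale invariant", {
  cm <- matrix(c(0L, 100L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  lib <- 1e6
  # direct evaluation of log2((y + prior)/(L + 2 prior) * 1e6)
  v <- cpm(cm, log = TRUE, prior = 0.5, lib_sizes = lib)
  expect_equal(v["g1", 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)

  # y = L * 1e-6 * 2^k with prior 0 gives CPM = 2^k exactly
  cm2 <- matrix(c(8L, 32L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  v2 <- cpm(cm2, log = FALSE, prior = 0, lib_sizes = 1e6)
  expect_equal(unname(v2[, 1]), c(8, 32))

  # doubling counts and library size leaves CPM unchanged
  sheet <- toy_sheet(2)
  cm3 <- toy_counts(sheet, 50)
  expect_equal(cpm(cm3, prior = 0), cpm(2L * cm3, prior = 0))

  expect_error(cpm(cm3, lib_sizes = c(0, 1, 1, 1)), "library size")
})

test_that("low-expression filter applies the CPM-in-enough-samples rule", {
  lib <- rep(1e6, 4)
  cm <- rbind(
    kept = c(2L, 0L, 2L, 3L),      # CPM 2,0,2,3 -> 3 samples >= 1
    dropped = c(1L, 0L, 0L, 0L),   # only 1 sample >= 1
    zero = c(0L, 0L, 0L, 0L))
  colnames(cm) <- paste0("s", 1:4)
  out <- filter_low_expression(cm, min_cpm = 1, min_samples = 3, lib_sizes = lib)
  expect_identical(rownames(out), "kept")

  # min_samples = 0 is the identity filter
  expect_identical(filter_low_expression(cm, min_samples = 0, lib_sizes = lib), cm)

  # idempotence
  sheet <- toy_sheet(3)
  cm2 <- toy_counts(sheet, 200)
  f1 <- filter_low_expression(cm2)
  expect_identical(filter_low_expression(f1, lib_sizes = colSums(cm2)[colnames(f1)]),
                   f1)
})

test_that("pairwise correlation has unit diagonal, symmetry and exact extremes", {
  sheet <- toy_sheet(2)
  lcm <- matrix(c(1, 2, 3, 3, 2, 1, 1, 2, 3, 2, 4, 6), 3, 4,
                dimnames = list(NULL, sheet$sample_id))
  qc <- pairwise_correlation(lcm, sheet)
  expect_equal(diag(qc$cor_matrix), setNames(rep(1, 4), sheet$sample_id))
  expect_equal(qc$cor_matrix, t(qc$cor_matrix))
  expect_equal(qc$cor_matrix[1, 2], -1)  # reversed vector
  expect_equal(qc$cor_matrix[1, 3], 1)

  expect_error(pairwise_correlation(matrix(1, 3, 2), toy_sheet(1)), "constant")
})

test_that("hierarchical clustering merges zero-distance samples first", {
  x <- cbind(s1 = c(0, 0), s2 = c(0, 0), s3 = c(10, 0))
  tree <- hierarchical_cluster(x)
  expect_equal(length(tree$order), 3)
  # first merge joins the two identical samples at height 0
  expect_equal(sort(-tree$merge[1, ]), c(1, 2))
  expect_equal(tree$height[1], 0)

  # forced merge order with distances (1, 10, 10)
  y <- cbind(a = 0, b = 1, c = 10)
  tree2 <- hierarchical_cluster(rbind(y, 0))
  expect_equal(sort(-tree2$merge[1, ]), c(1, 2))
})

test_that("leading-logFC MDS preserves simple geometries", {
  # duplicated sample: coincident points
  x <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(5, 5, 5))
  co <- mds_leading_logfc(x, top = 3, k = 2)
  expect_lt(max(abs(co["s1", ] - co["s2", ])), 1e-6)

  # 3 samples on a line: recovered 1-D configuration preserves distances
  z <- rbind(c(0, 1, 3))  # one gene, positions 0,1,3
  z <- rbind(z, 0)        # second constant gene
  colnames(z) <- c("a", "b", "c")
  co2 <- mds_leading_logfc(z, top = 2, k = 2)
  d_in <- as.matrix(dist(t(z))) / sqrt(2)  # rms over top-2 genes
  d_out <- as.matrix(dist(co2))
  expect_equal(unname(d_out), unname(d_in), tolerance = 1e-8)
})

test_that("MDS double-centering reconstructs Euclidean-embeddable distances", {
  set.seed(1)
  pts <- matrix(rnorm(6 * 3), 3, 6, dimnames = list(NULL, paste0("s", 1:6)))
  co <- suppressWarnings(mds_leading_logfc(pts, top = 3, k = 5))
  d_in <- vapply(1:6, function(i) vapply(1:6, function(j)
    sqrt(mean(sort(abs(pts[, i] - pts[, j]), decreasing = TRUE)[1:3]^2)), 0), rep(0, 6))
  expect_equal(unname(as.matrix(dist(co))), unname(d_in), tolerance = 1e-6)
})

test_that("outlier flagging is empty under homogeneity and catches a planted outlier", {
  co <- simulate_cohort(sim_config(n_genes = 500, seed = 21))
  lcm <- cpm(filter_low_expression(co$counts), log = TRUE)
  qc <- pairwise_correlation(lcm, co$sheet)
  expect_length(flag_outliers(qc), 0)

  # shuffle the gene labels of one sample: its correlation to all collapses
  lcm2 <- lcm
  set.seed(22)
  lcm2[, 5] <- sample(lcm2[, 5])
  qc2 <- pairwise_correlation(lcm2, co$sheet)
  expect_identical(flag_outliers(qc2), colnames(lcm2)[5])
})

test_that("outlier statistic degenerates gracefully at n = 2", {
  qc <- list(cor_matrix = matrix(c(1, 0.9, 0.9, 1), 2, 2,
                                 dimnames = list(c("a", "b"), c("a", "b"))))
  expect_warning(out <- flag_outliers(qc), "fewer than three")
  expect_length(out, 0)
})
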