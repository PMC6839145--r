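test_that("paired design has the expected shape and tested coefficient", {
  sheet <- toy_sheet(5)
  X <- build_design(sheet, "discordant_group")
  expect_equal(dim(X), c(10, 6))  # intercept + 4 pair + case
  expect_equal(qr(X)$rank, 6)
  expect_equal(colnames(X)[attr(X, "test_coef")], "case")

  # a concordant pair offered to the discordant analysis is dropped
  sheet2 <- toy_sheet(3, n_conc = 1)
  expect_warning(X2 <- build_design(sheet2, "discordant_group"), "dropped")
  expect_equal(nrow(X2), 6)
  expect_false(any(grepl("P04", rownames(X2))))

  # all-control input cannot estimate a case effect
  expect_error(suppressWarnings(build_design(toy_sheet(0, n_ctrl = 3), "case_control")),
               "constant")
})

test_that("case-control design keeps concordant pairs estimable", {
  sheet <- toy_sheet(2, n_ctrl = 2, n_conc = 2)
  X <- build_design(sheet, "case_control")
  expect_equal(nrow(X), 12)
  expect_equal(qr(X)$rank, ncol(X))
  expect_false(is.na(attr(X, "test_coef")))
})

test_that("Benjamini-Hochberg follows the step-up formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.1, NA)), "NA")
  # monotone non-decreasing after sorting by p
  set.seed(51)
  p <- runif(50)
  fdr <- benjamini_hochberg(p)
  expect_true(all(diff(fdr[order(p)]) >= -1e-12))
  expect_true(all(fdr >= p))
})

test_that("within-pair logFC is exact for identity and ratio cases", {
  sheet <- toy_sheet(2)
  cm <- toy_counts(sheet, 50)
  # make the second pair identical co-twins
  cm[, "P02b"] <- cm[, "P02a"]
  suppressWarnings(ppl <- per_pair_logfc(cm, sheet, norm_factors = setNames(rep(1, 4), colnames(cm))))
  expect_equal(unname(ppl[, "P02"]), rep(0, 50))

  # case twin at 4x the co-twin with equal effective library sizes
  big <- rbind(g1 = c(40000L, 10000L, 40000L, 10000L),
               g2 = c(10000L, 40000L, 10000L, 40000L))
  colnames(big) <- sheet$sample_id
  nf <- setNames(rep(1, 4), colnames(big))
  ppl2 <- per_pair_logfc(big, sheet, norm_factors = nf)
  expect_equal(unname(ppl2["g1", "P01"]), 2, tolerance = 1e-3)

  # singleton pairs are skipped with a warning
  sheet3 <- rbind(toy_sheet(2),
                  data.frame(sample_id = "S01a", pair_id = "S01",
                             group = "control", case = 0L, sex = "M"))
  cm3 <- toy_counts(sheet3, 30)
  expect_warning(ppl3 <- per_pair_logfc(cm3, sheet3), "singleton")
  expect_equal(ncol(ppl3), 2)
})

test_that("direction consistency follows the all-pairs sign rule", {
  m <- rbind(up = c(1, 2, 0.5, 0.1, 3),
             mixed = c(1, -1, 1, 1, 1),
             down = c(-1, -2, -0.5, -0.1, -3),
             zero = c(1, 0, 1, 1, 1))
  colnames(m) <- paste0("P", 1:5)
  attr(m, "groups") <- setNames(rep("discordant", 5), colnames(m))
  expect_equal(unname(direction_consistency(m)),
               c("up", "none", "down", "none"))
})

test_that("LRT results are well-formed: D >= 0, sorted, annotated", {
  co <- simulate_cohort(sim_config(n_genes = 300, n_de_genes = 10, de_logfc = 3,
                                   seed = 52))
  f <- filter_low_expression(co$counts)
  de <- suppressWarnings(lrt_case(f, co$sheet, "discordant_group"))
  expect_true(all(de$p_value > 0 & de$p_value <= 1))
  expect_true(!is.unsorted(de$p_value))
  expect_true(all(de$fdr >= de$p_value - 1e-12))
  expect_true(all(de$consistent_direction %in% c("up", "down", "none")))
  # strong positive simulated effects come out with positive per-pair signs
  top_true <- intersect(de$gene_id[1:5], co$truth$de_genes$gene_id)
  expect_true(all(de$consistent_direction[match(top_true, de$gene_id)] == "up"))

  # case-control run on the same cohort carries no direction annotation
  de_cc <- suppressWarnings(lrt_case(f, co$sheet, "case_control"))
  expect_true(all(is.na(de_cc$consistent_direction)))
  expect_equal(nrow(de_cc), nrow(f))
})
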