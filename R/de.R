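#' Build the paired design matrix
#'
#' Gene counts are regressed on `pair` (categorical twin-pair membership,
#' reference pair dropped) and `case` (binary affection status); the tested
#' coefficient is `case`. `discordant_group` retains complete discordant pairs
#' only; `case_control` retains all complete pairs across the three study
#' groups. Samples without a usable configuration (singletons, or
#' non-discordant pairs in the discordant analysis) are dropped with a
#' warning. Columns made unestimable by aliasing are pivoted out with a
#' warning; an aliased or constant `case` column is an error.
#'
#' @param sheet Sample sheet.
#' @param analysis `"discordant_group"` or `"case_control"`.
#' @return Numeric design matrix with attributes `test_coef` (column index of
#'   `case`), `samples` (retained sample ids, row order) and `sheet` (the
#'   retained sheet rows).
#' @export
build_design <- function(sheet, analysis = c("discordant_group", "case_control")) {
  analysis <- match.arg(analysis)
  sheet <- validate_sample_sheet(sheet)
  keep_pairs <- complete_pairs(sheet)
  use <- sheet$pair_id %in% keep_pairs
  if (analysis == "discordant_group") use <- use & sheet$group == "discordant"
  if (any(!use)) {
    warning(sum(!use), " sample(s) dropped (singleton or outside the ",
            analysis, " analysis)")
  }
  sub <- sheet[use, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no usable samples for ", analysis)
  if (length(unique(sub$case)) < 2L) stop("case column is constant; design is degenerate")
  pair <- factor(sub$pair_id)
  X <- stats::model.matrix(~ pair + case, data = data.frame(pair = pair, case = sub$case))
  colnames(X)[1L] <- "intercept"
  dq <- qr(X)
  if (dq$rank < ncol(X)) {
    aliased <- colnames(X)[dq$pivot[-seq_len(dq$rank)]]
    if ("case" %in% aliased) stop("case is confounded with the pair blocks")
    warning("dropping aliased design column(s): ", paste(aliased, collapse = ", "))
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
  }
  rownames(X) <- sub$sample_id
  attr(X, "test_coef") <- match("case", colnames(X))
  attr(X, "samples") <- sub$sample_id
  attr(X, "sheet") <- sub
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  X
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH: `fdr_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and mapped
#' back to the input order (delegates to [stats::p.adjust()]).
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of BH-adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p)) stop("NA p-values are not allowed")
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Paired NB-GLM likelihood-ratio test for the case effect
#'
#' The full workflow behind the differential-expression tables: TMM
#' normalisation, Cox-Reid tagwise dispersion estimation, per-gene NB GLM fits
#' of the full (`pair + case`) and reduced (`pair`) models with shared
#' dispersions and offsets, the likelihood-ratio statistic
#' `D = 2 (ll_full - ll_reduced)` referred to chi-square with 1 df, and BH
#' FDR. Results are sorted by p-value (ties broken by gene id). For the
#' discordant analysis each gene is annotated with whether its within-pair
#' log fold change has a consistent sign across all discordant pairs.
#'
#' @param counts Filtered gene x sample count matrix.
#' @param sheet Sample sheet.
#' @param analysis `"discordant_group"` or `"case_control"`.
#' @param prior_df Dispersion shrinkage weight, see [estimate_dispersions()].
#' @param extra_covariates Optional numeric matrix of additional sample-level
#'   covariates (e.g. surrogate variables), rows matching the retained
#'   samples.
#' @param dispersion Optional fixed per-gene dispersion(s), bypassing
#'   estimation.
#' @return A `data.frame` of class `de_result` with columns `gene_id`,
#'   `logFC` (log2), `logCPM`, `p_value`, `fdr`, `consistent_direction`
#'   (`"up"`, `"down"`, `"none"`, or `NA` for the case-control analysis) and
#'   `converged`. The design, normalisation factors and dispersion object are
#'   attached as attributes.
#' @export
lrt_case <- function(counts, sheet,
                     analysis = c("discordant_group", "case_control"),
                     prior_df = 10, extra_covariates = NULL,
                     dispersion = NULL) {
  analysis <- match.arg(analysis)
  X <- build_design(sheet, analysis)
  samples <- attr(X, "samples")
  missing_s <- setdiff(samples, colnames(counts))
  if (length(missing_s)) stop("samples absent from count matrix: ",
                              paste(missing_s, collapse = ", "))
  cm <- counts[, samples, drop = FALSE]
  if (!is.null(extra_covariates)) {
    extra_covariates <- as.matrix(extra_covariates)
    X <- augment_design(X, extra_covariates)
  }
  test_coef <- attr(X, "test_coef")

  lib <- colSums(cm)
  nf <- tmm_factors(cm, lib_sizes = lib)
  eff_lib <- lib * nf
  offsets <- log(eff_lib)

  if (is.null(dispersion)) {
    disp <- estimate_dispersions(cm, X, norm_factors = nf, prior_df = prior_df,
                                 lib_sizes = lib)
    phi <- disp$tagwise
  } else {
    disp <- NULL
    phi <- rep_len(dispersion, nrow(cm))
  }

  full <- .nb_fit_matrix(cm, X, offsets, phi)
  reduced <- .nb_fit_matrix(cm, X[, -test_coef, drop = FALSE], offsets, phi)
  D <- pmax(2 * (full$loglik - reduced$loglik), 0)
  p <- pchisq(D, df = 1, lower.tail = FALSE)

  res <- data.frame(
    gene_id = rownames(cm),
    logFC = full$coefficients[, test_coef] / log(2),
    logCPM = rowMeans(cpm(cm, log = TRUE, lib_sizes = eff_lib)),
    p_value = p,
    fdr = benjamini_hochberg(p),
    consistent_direction = NA_character_,
    converged = full$converged & reduced$converged,
    stringsAsFactors = FALSE, row.names = NULL)

  if (analysis == "discordant_group") {
    ppl <- per_pair_logfc(cm, attr(X, "sheet"), norm_factors = nf)
    res$consistent_direction <- direction_consistency(ppl)[res$gene_id]
  }
  res <- res[order(res$p_value, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("de_result", "data.frame"),
            analysis = analysis, design = X, norm_factors = nf,
            dispersion = disp)
}

#' Within-pair log fold changes
#'
#' For each complete pair and each gene,
#' `logFC = log2((y_case + 0.5)/(L_case + 1)) - log2((y_cotwin + 0.5)/(L_cotwin + 1))`
#' using effective (TMM-scaled) library sizes. In discordant pairs the
#' contrast is case versus unaffected co-twin; in concordant-case and control
#' pairs it is the second versus the first twin in sample-sheet order.
#' Singleton pairs are skipped with a warning.
#'
#' @param counts Gene x sample count matrix.
#' @param sheet Sample sheet covering the columns of `counts`.
#' @param norm_factors Optional TMM factors for the samples of `counts`.
#' @return Gene x pair matrix of log2 fold changes with a `groups` attribute
#'   mapping pair ids to study groups.
#' @export
per_pair_logfc <- function(counts, sheet, norm_factors = NULL) {
  sheet <- sheet[sheet$sample_id %in% colnames(counts), , drop = FALSE]
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  eff_lib <- colSums(counts) * norm_factors[colnames(counts)]
  pairs <- unique(sheet$pair_id)
  singles <- setdiff(pairs, complete_pairs(sheet))
  if (length(singles)) {
    warning("skipping singleton pair(s): ", paste(singles, collapse = ", "))
    pairs <- setdiff(pairs, singles)
  }
  if (!length(pairs)) stop("no complete pairs")
  out <- matrix(NA_real_, nrow(counts), length(pairs),
                dimnames = list(rownames(counts), pairs))
  groups <- character(length(pairs)); names(groups) <- pairs
  for (pid in pairs) {
    rows <- sheet[sheet$pair_id == pid, ]
    groups[pid] <- rows$group[1L]
    if (rows$group[1L] == "discordant") {
      s1 <- rows$sample_id[rows$case == 1L]
      s2 <- rows$sample_id[rows$case == 0L]
    } else {
      s1 <- rows$sample_id[2L]
      s2 <- rows$sample_id[1L]
    }
    out[, pid] <- log2((counts[, s1] + 0.5) / (eff_lib[s1] + 1)) -
      log2((counts[, s2] + 0.5) / (eff_lib[s2] + 1))
  }
  attr(out, "groups") <- groups
  out
}

#' Direction consistency of within-pair effects
#'
#' `"up"` when every discordant pair's logFC is positive, `"down"` when every
#' one is negative, `"none"` otherwise (a zero in any pair gives `"none"`).
#'
#' @param ppl Gene x pair logFC matrix from [per_pair_logfc()]; only
#'   discordant-pair columns are used.
#' @param genes Optional subset of gene ids.
#' @return Named character vector over genes.
#' @export
direction_consistency <- function(ppl, genes = NULL) {
  groups <- attr(ppl, "groups")
  cols <- if (is.null(groups)) colnames(ppl) else names(groups)[groups == "discordant"]
  if (length(cols) < 2L) stop("at least two discordant pairs required")
  m <- ppl[, cols, drop = FALSE]
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  res <- ifelse(rowSums(m > 0) == ncol(m), "up",
                ifelse(rowSums(m < 0) == ncol(m), "down", "none"))
  setNames(res, rownames(m))
}

#' @export
print.de_result <- function(x, n = 10L, ...) {
  cat("de_result (", attr(x, "analysis"), "): ", nrow(x), " genes; ",
      sum(x$fdr < 0.1), " at FDR < 0.1\n", sep = "")
  print.data.frame(utils::head(x, n))
  invisible(x)
}
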