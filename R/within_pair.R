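#' Pool absolute within-pair log fold changes by study group
#'
#' For each study group the absolute within-pair logFCs are pooled over all
#' genes and complete pairs, the group means recorded, and every group pair
#' compared by Welch t and two-sample KS tests. Values within a group are
#' treated as exchangeable despite gene-gene dependence; the returned object
#' carries an explicit caveat note to that effect.
#'
#' @param ppl Gene x pair logFC matrix from [per_pair_logfc()].
#' @param sheet Sample sheet (used only when `ppl` lacks a `groups`
#'   attribute).
#' @return List of class `group_logfc` with `values` (named list of pooled
#'   `|logFC|` vectors per group), `means`, `tests` (data.frame of pairwise
#'   group comparisons: t, t_p, ks_D, ks_p) and `note`.
#' @export
collect_abs_logfc <- function(ppl, sheet = NULL) {
  groups <- attr(ppl, "groups")
  if (is.null(groups)) {
    stopifnot(!is.null(sheet))
    groups <- vapply(colnames(ppl), function(pid)
      sheet$group[sheet$pair_id == pid][1L], "")
  }
  present <- unique(groups)
  values <- lapply(present, function(g) {
    as.vector(abs(ppl[, names(groups)[groups == g], drop = FALSE]))
  })
  names(values) <- present
  if (any(vapply(values, length, 1L) == 0L)) stop("study group with zero complete pairs")
  means <- vapply(values, mean, 0)
  combos <- if (length(present) >= 2L) utils::combn(present, 2L) else NULL
  tests <- NULL
  if (!is.null(combos)) {
    tests <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
      a <- values[[combos[1L, i]]]; b <- values[[combos[2L, i]]]
      tt <- welch_t(a, b)
      ks <- ks_two_sample(a, b)
      data.frame(group_a = combos[1L, i], group_b = combos[2L, i],
                 t = tt[["t"]], t_p = tt[["p"]],
                 ks_D = ks[["D"]], ks_p = ks[["p"]],
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(values = values, means = means, tests = tests,
                 note = paste("pooled |logFC| values are dependent across genes;",
                              "test p-values are descriptive, not inferential")),
            class = "group_logfc")
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value (delegates to [stats::t.test()]).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return Named vector `c(t, p)`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (var(a) == 0 && var(b) == 0) stop("both samples have zero variance")
  tt <- t.test(a, b, var.equal = FALSE)
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the exact supremum of `|F_a - F_b|` over the pooled order
#' statistics; the p-value uses the asymptotic Kolmogorov distribution with
#' effective size `n_a n_b / (n_a + n_b)` (delegates to [stats::ks.test()]
#' with `exact = FALSE`; ties are tolerated).
#'
#' @param a,b Non-empty numeric vectors.
#' @return Named vector `c(D, p)`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  ks <- suppressWarnings(ks.test(a, b, exact = FALSE))
  c(D = unname(ks$statistic), p = ks$p.value)
}

#' @export
print.group_logfc <- function(x, ...) {
  cat("group mean |logFC|:\n")
  print(round(x$means, 4))
  if (!is.null(x$tests)) print(x$tests)
  cat("note:", x$note, "\n")
  invisible(x)
}
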