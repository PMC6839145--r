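#' Read a gene-by-sample count matrix
#'
#' Counts are stored as TSV with gene identifiers in the first column and one
#' column per sample. Values must be non-negative integers; duplicate gene
#' identifiers are rejected.
#'
#' @param path Path to a tab-separated count file.
#' @return Integer matrix (genes x samples) with gene ids as row names and
#'   sample ids as column names. Library sizes are the column sums.
#' @export
read_counts <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("count file must have a gene id column and at least one sample")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in ", path, ": ", paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- ids
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

validate_counts <- function(counts) {
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  }
  invisible(counts)
}

#' Write a count matrix to TSV
#'
#' @param counts Integer matrix as returned by [read_counts()].
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet drives every design matrix. Required columns:
#' `sample_id`, `pair_id`, `group` (one of `discordant`, `concordant_case`,
#' `control`), `case` (0/1) and `sex`.
#'
#' Validation enforces the twin structure: at most two samples per pair;
#' complete discordant pairs have exactly one case, concordant-case pairs two,
#' control pairs none.
#'
#' @param path Path to a tab-separated sample sheet.
#' @return A validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet `data.frame` to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "pair_id", "group", "case", "sex")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$pair_id <- as.character(sheet$pair_id)
  sheet$case <- as.integer(sheet$case)
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids in sample sheet")
  ok_groups <- c("discordant", "concordant_case", "control")
  if (!all(sheet$group %in% ok_groups)) {
    stop("group must be one of: ", paste(ok_groups, collapse = ", "))
  }
  if (!all(sheet$case %in% c(0L, 1L))) stop("case must be 0 or 1")
  for (pid in unique(sheet$pair_id)) {
    rows <- sheet[sheet$pair_id == pid, ]
    if (nrow(rows) > 2L) stop("pair '", pid, "' has more than two samples")
    if (length(unique(rows$group)) > 1L) stop("pair '", pid, "' spans multiple groups")
    if (nrow(rows) == 2L) {
      ncase <- sum(rows$case)
      g <- rows$group[1L]
      if (g == "discordant" && ncase != 1L)
        stop("discordant pair '", pid, "' must have exactly one case (found ", ncase, ")")
      if (g == "concordant_case" && ncase != 2L)
        stop("concordant_case pair '", pid, "' must have two cases (found ", ncase, ")")
      if (g == "control" && ncase != 0L)
        stop("control pair '", pid, "' must have no cases (found ", ncase, ")")
    }
  }
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Complete twin pairs in a sample sheet
#'
#' @param sheet Sample sheet.
#' @return Character vector of pair ids having both co-twins present.
#' @export
complete_pairs <- function(sheet) {
  tab <- table(sheet$pair_id)
  names(tab)[tab == 2L]
}

#' Read a GMT gene-set file
#'
#' Standard MSigDB-style GMT: one set per line, tab-separated fields
#' `name`, `description`, then member gene ids.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors with a `description` attribute
#'   (named character vector, one entry per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short)) stop("GMT line ", which(short)[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate set name in GMT: ", nm[duplicated(nm)][1L])
  sets <- lapply(fields, function(f) f[-(1:2)])
  empty <- vapply(sets, function(s) all(!nzchar(s)), TRUE)
  if (any(empty)) stop("GMT set '", nm[empty][1L], "' has no members")
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(fields, `[[`, "", 2L), nm)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (optionally with a
#'   `description` attribute) to serialise.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a methylation Beta matrix with its probe manifest
#'
#' Beta values are proportions in (0,1); values at or outside the boundary are
#' clamped to `[eps, 1 - eps]` with a warning (the clamp keeps the M-value
#' transform finite). The manifest is a 4-column TSV `chrom`, `position`
#' (1-based), `probe_id`, `gene_id`; every probe in the Beta matrix must have a
#' manifest row, and manifest probes absent from the matrix are dropped with a
#' warning.
#'
#' @param beta_path Path to the Beta-value TSV (probe ids in first column).
#' @param manifest_path Path to the probe manifest TSV.
#' @param eps Boundary clamp for Beta values.
#' @return A list of class `methylation_set` with elements `beta`
#'   (probe x sample matrix) and `manifest` (data.frame ordered by
#'   chromosome and position).
#' @export
read_methylation <- function(beta_path, manifest_path, eps = 1e-6) {
  tab <- read.delim(beta_path, check.names = FALSE, stringsAsFactors = FALSE)
  probes <- as.character(tab[[1L]])
  if (anyDuplicated(probes)) stop("duplicate probe ids in ", beta_path)
  beta <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(beta) <- probes
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("chrom", "position", "probe_id", "gene_id")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  methylation_set(beta, manifest, eps = eps)
}

#' @rdname read_methylation
#' @param beta Probe x sample matrix of Beta values.
#' @param manifest Probe manifest data.frame.
#' @export
methylation_set <- function(beta, manifest, eps = 1e-6) {
  manifest$probe_id <- as.character(manifest$probe_id)
  if (any(manifest$position < 0)) stop("manifest positions must be non-negative")
  missing_probes <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing_probes)) {
    stop(length(missing_probes), " probe(s) missing from manifest, e.g. '",
         missing_probes[1L], "'")
  }
  extra <- setdiff(manifest$probe_id, rownames(beta))
  if (length(extra)) {
    warning(length(extra), " manifest probe(s) absent from Beta matrix; dropped")
    manifest <- manifest[manifest$probe_id %in% rownames(beta), , drop = FALSE]
  }
  n_clamped <- sum(beta <= 0 | beta >= 1)
  if (n_clamped > 0L) {
    warning(n_clamped, " Beta value(s) outside (0,1) clamped to [",
            format(eps), ", ", format(1 - eps), "]")
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  manifest <- manifest[order(manifest$chrom, manifest$position), , drop = FALSE]
  rownames(manifest) <- NULL
  structure(list(beta = beta, manifest = manifest), class = "methylation_set")
}

#' @export
print.methylation_set <- function(x, ...) {
  cat("methylation_set:", nrow(x$beta), "probes x", ncol(x$beta), "samples,",
      length(unique(x$manifest$gene_id)), "genes\n")
  invisible(x)
}

#' Write a result table to TSV
#'
#' @param results A data.frame.
#' @param path Output path.
#' @export
write_table <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
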