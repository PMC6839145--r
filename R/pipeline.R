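#' Pipeline run configuration
#'
#' Collects input paths and stage parameters for [run_all()]. Only `counts`
#' and `sheet` are required; methylation and gene-set stages run when their
#' inputs are present.
#'
#' @param counts,sheet Paths to the count matrix and sample sheet TSVs.
#' @param beta,manifest Optional paths to the Beta matrix and probe manifest.
#' @param gmt Optional path to a GMT gene-set file.
#' @param analysis `"discordant_group"` or `"case_control"`.
#' @param fdr_threshold FDR level used for reporting (default 0.1).
#' @param min_cpm,min_samples Low-expression filter parameters.
#' @param dist,top_k Integration parameters (bp window, top slice).
#' @param n_perm Gene-set permutations.
#' @param sva Estimate and adjust for surrogate variables?
#' @param male_only Restrict to complete male pairs?
#' @param drop_outliers Remove QC-flagged outlier samples (whole pairs are
#'   never split; the co-twin of a removed sample is removed too)?
#' @param seed Master seed; per-stage streams are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(counts, sheet, beta = NULL, manifest = NULL,
                       gmt = NULL,
                       analysis = c("discordant_group", "case_control"),
                       fdr_threshold = 0.1, min_cpm = 1, min_samples = 3,
                       dist = 2000, top_k = 20, n_perm = 10000,
                       sva = FALSE, male_only = FALSE,
                       drop_outliers = FALSE, seed = 1L) {
  analysis <- match.arg(analysis)
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  structure(list(counts = counts, sheet = sheet, beta = beta,
                 manifest = manifest, gmt = gmt, analysis = analysis,
                 fdr_threshold = fdr_threshold, min_cpm = min_cpm,
                 min_samples = min_samples, dist = dist, top_k = top_k,
                 n_perm = n_perm, sva = sva, male_only = male_only,
                 drop_outliers = drop_outliers, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# deterministic per-stage seed derived from the master seed and stage name
.stage_seed <- function(seed, stage) {
  (seed * 1000L + sum(utf8ToInt(stage))) %% .Machine$integer.max
}

#' Restrict a sample sheet to male pairs
#'
#' Retains complete pairs in which both co-twins are male; pairs are never
#' split.
#'
#' @param sheet Sample sheet.
#' @param male_only When `FALSE` the sheet is returned unchanged.
#' @return Filtered sample sheet.
#' @export
subgroup_filter <- function(sheet, male_only = TRUE) {
  if (!male_only) return(sheet)
  keep <- vapply(unique(sheet$pair_id), function(pid) {
    rows <- sheet[sheet$pair_id == pid, ]
    nrow(rows) == 2L && all(rows$sex == "M")
  }, TRUE)
  out <- sheet[sheet$pair_id %in% names(keep)[keep], , drop = FALSE]
  if (nrow(out) == 0L) stop("no complete male pairs remain")
  rownames(out) <- NULL
  out
}

#' Compare gene ranks between two DE runs
#'
#' Sensitivity report: for each gene in both tables, the rank (by p-value) in
#' each run and the rank difference.
#'
#' @param de_a,de_b Two `de_result` tables.
#' @return Data.frame `gene_id`, `rank_a`, `rank_b`, `rank_diff`, sorted by
#'   `rank_a`.
#' @export
compare_de_ranks <- function(de_a, de_b) {
  shared <- intersect(de_a$gene_id, de_b$gene_id)
  ra <- rank_genes(de_a)[shared]
  rb <- rank_genes(de_b)[shared]
  out <- data.frame(gene_id = shared, rank_a = as.numeric(ra),
                    rank_b = as.numeric(rb),
                    rank_diff = as.numeric(rb - ra),
                    stringsAsFactors = FALSE)
  out[order(out$rank_a), , drop = FALSE]
}

#' Run the full pipeline
#'
#' Executes filter, QC, (optional) surrogate-variable estimation, paired
#' differential expression, within-pair group comparisons, gene-set
#' enrichment (when a GMT is supplied) and the expression-methylation
#' integration (when methylation inputs are supplied). All result tables plus
#' a JSON run manifest (configuration snapshot, input checksums, per-stage
#' row counts, collected warnings) are written to `out_dir`. Outputs are a
#' pure function of the inputs and the seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of in-memory results.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))

  counts <- read_counts(config$counts)
  sheet <- read_sample_sheet(config$sheet)
  sheet <- sheet[sheet$sample_id %in% colnames(counts), , drop = FALSE]
  if (config$male_only) sheet <- subgroup_filter(sheet, TRUE)
  counts <- counts[, sheet$sample_id, drop = FALSE]

  ## filter
  filtered <- filter_low_expression(counts, config$min_cpm, config$min_samples)

  ## qc
  qc <- withCallingHandlers(qc_report(filtered, sheet),
                            warning = function(w) { note(w); invokeRestart("muffleWarning") })
  if (config$drop_outliers && length(qc$outlier_samples)) {
    drop_pairs <- unique(sheet$pair_id[sheet$sample_id %in% qc$outlier_samples])
    sheet <- sheet[!sheet$pair_id %in% drop_pairs, , drop = FALSE]
    counts <- counts[, sheet$sample_id, drop = FALSE]
    filtered <- filter_low_expression(counts, config$min_cpm, config$min_samples)
  }
  write_table(data.frame(metric = c("median_within_pair_r", "median_unrelated_r"),
                         value = c(qc$median_within_pair_r, qc$median_unrelated_r)),
              file.path(out_dir, "qc_summary.tsv"))
  write_table(as.data.frame(qc$mds), file.path(out_dir, "qc_mds.tsv"))

  ## optional SVA
  extra <- NULL
  svs <- NULL
  if (config$sva) {
    X0 <- suppressWarnings(build_design(sheet, config$analysis))
    lcm <- cpm(filtered[, attr(X0, "samples"), drop = FALSE], log = TRUE)
    svs <- estimate_svs(lcm, X0, seed = .stage_seed(config$seed, "sva"))
    if (svs$n_sv > 0L) extra <- svs$sv
    write_table(data.frame(sample_id = rownames(svs$sv), svs$sv),
                file.path(out_dir, "surrogate_variables.tsv"))
  }

  ## paired DE
  de <- withCallingHandlers(
    lrt_case(filtered, sheet, config$analysis, extra_covariates = extra),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })
  write_table(de[, c("gene_id", "logFC", "logCPM", "p_value", "fdr",
                     "consistent_direction")],
              file.path(out_dir, "de.tsv"))

  ## within-pair comparisons across all groups
  ppl <- withCallingHandlers(per_pair_logfc(filtered, sheet),
                             warning = function(w) { note(w); invokeRestart("muffleWarning") })
  wp <- collect_abs_logfc(ppl)
  wp_tab <- data.frame(group = names(wp$means), mean_abs_logfc = as.numeric(wp$means))
  write_table(wp_tab, file.path(out_dir, "within_pair_means.tsv"))
  if (!is.null(wp$tests)) {
    tests <- wp$tests
    attr(tests, "note") <- wp$note
    write_table(tests, file.path(out_dir, "within_pair_tests.tsv"))
  }

  ## gene sets
  gse <- NULL
  if (!is.null(config$gmt)) {
    gmt <- read_gmt(config$gmt)
    gse <- run_collection(de, gmt, n_perm = config$n_perm,
                          seed = .stage_seed(config$seed, "gse"))
    write_table(gse, file.path(out_dir, "gse.tsv"))
  }

  ## integration
  integ <- NULL
  if (!is.null(config$beta) && !is.null(config$manifest)) {
    meth <- withCallingHandlers(read_methylation(config$beta, config$manifest),
                                warning = function(w) { note(w); invokeRestart("muffleWarning") })
    marm <- withCallingHandlers(
      run_methylation(meth, sheet, config$analysis, dist = config$dist),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
    integ <- integrate_omics(de, marm$probes, meth, filtered,
                             top_k = config$top_k)
    write_table(integ, file.path(out_dir, "integration.tsv"))
    write_table(attr(integ, "top"), file.path(out_dir, "integration_top.tsv"))
  }

  ## manifest
  inputs <- Filter(Negate(is.null),
                   config[c("counts", "sheet", "beta", "manifest", "gmt")])
  manifest <- list(
    package_version = as.character(packageVersion("twindiff")),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    rows = list(genes_prefilter = nrow(counts), genes_postfilter = nrow(filtered),
                samples = ncol(counts), de = nrow(de),
                gse = if (is.null(gse)) 0L else nrow(gse),
                integration = if (is.null(integ)) 0L else nrow(integ)),
    warnings = warnings_log)
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  file.rename(tmp, file.path(out_dir, "manifest.json"))

  invisible(list(qc = qc, de = de, within_pair = wp, gse = gse,
                 integration = integ, svs = svs, manifest = manifest))
}
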