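#' Configuration for the synthetic twin-cohort generator
#'
#' Defaults describe a desk-scale cohort with the structure of a typical
#' discordant-MZ-twin RNA-seq study: 16 complete pairs (5 discordant,
#' 4 concordant-case, 8 control), 2000 genes of which 50 are differentially
#' expressed at log2 fold change 2 in cases, per-pair expression effects of
#' sd 0.5 (log2), per-gene NB dispersions from Gamma(shape 2, rate 10) (mean
#' 0.2, typical for blood RNA-seq), and a sparse array-style methylation
#' layer with AR(1)-correlated probe signal.
#'
#' @param n_pairs_discordant,n_pairs_concordant_case,n_pairs_control Number of
#'   complete twin pairs per study group.
#' @param n_singletons Number of additional co-twin-less samples (excluded
#'   from all paired analyses; default 0).
#' @param n_genes,n_de_genes Total genes and truly differentially expressed
#'   genes (case effect).
#' @param de_logfc True case log2 fold change for DE genes.
#' @param pair_effect_sd SD (log2 units) of per-pair, per-gene shared effects.
#' @param baseline_logcpm_range Range of uniform baseline expression (log2 CPM).
#' @param dispersion_shape,dispersion_rate Gamma hyperparameters for per-gene
#'   NB dispersions.
#' @param library_size_range Range (reads) of the generative library-size
#'   offset.
#' @param n_probes_per_gene_mean Poisson mean for CpG probes per gene (genes
#'   drawing zero probes are absent from the methylation assay).
#' @param meth_case_delta_m Case shift on the M-value scale for differentially
#'   methylated genes.
#' @param meth_spatial_rho AR(1) correlation of probe-level M noise along the
#'   genome within a gene, in [0, 1).
#' @param meth_noise_sd Marginal SD of the AR(1) M-value noise.
#' @param probe_spacing_bp Distance between consecutive probes of a gene.
#' @param n_linked_genes Genes given BOTH an expression and a methylation case
#'   effect (must not exceed `n_de_genes`; default `min(10, n_de_genes)`).
#' @param seed Integer seed; the whole cohort is deterministic given the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs_discordant = 5L,
                       n_pairs_concordant_case = 4L,
                       n_pairs_control = 8L,
                       n_singletons = 0L,
                       n_genes = 2000L,
                       n_de_genes = 50L,
                       de_logfc = 2,
                       pair_effect_sd = 0.5,
                       baseline_logcpm_range = c(0, 10),
                       dispersion_shape = 2,
                       dispersion_rate = 10,
                       library_size_range = c(1e6, 2e6),
                       n_probes_per_gene_mean = 3,
                       meth_case_delta_m = 1.5,
                       meth_spatial_rho = 0.6,
                       meth_noise_sd = 0.5,
                       probe_spacing_bp = 500L,
                       n_linked_genes = NULL,
                       seed = 1L) {
  if (is.null(n_linked_genes)) n_linked_genes <- min(10L, n_de_genes)
  cfg <- list(
    n_pairs_discordant = as.integer(n_pairs_discordant),
    n_pairs_concordant_case = as.integer(n_pairs_concordant_case),
    n_pairs_control = as.integer(n_pairs_control),
    n_singletons = as.integer(n_singletons),
    n_genes = as.integer(n_genes),
    n_de_genes = as.integer(n_de_genes),
    de_logfc = de_logfc,
    pair_effect_sd = pair_effect_sd,
    baseline_logcpm_range = baseline_logcpm_range,
    dispersion_shape = dispersion_shape,
    dispersion_rate = dispersion_rate,
    library_size_range = library_size_range,
    n_probes_per_gene_mean = n_probes_per_gene_mean,
    meth_case_delta_m = meth_case_delta_m,
    meth_spatial_rho = meth_spatial_rho,
    meth_noise_sd = meth_noise_sd,
    probe_spacing_bp = as.integer(probe_spacing_bp),
    n_linked_genes = as.integer(n_linked_genes),
    seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_pairs_discordant >= 0, n_pairs_concordant_case >= 0,
              n_pairs_control >= 0, n_singletons >= 0,
              is.finite(de_logfc), pair_effect_sd >= 0,
              dispersion_shape > 0, dispersion_rate > 0,
              meth_spatial_rho >= 0, meth_spatial_rho < 1,
              meth_noise_sd >= 0, probe_spacing_bp > 0,
              n_probes_per_gene_mean >= 0)
    if (n_genes < 1L) stop("n_genes must be at least 1")
    if (n_de_genes > n_genes) stop("n_de_genes cannot exceed n_genes")
    if (n_linked_genes > n_de_genes) stop("n_linked_genes cannot exceed n_de_genes")
  })
  structure(cfg, class = "sim_config")
}

# AR(1) noise matrix (probes x samples) with marginal sd `sd`, correlation
# `rho` between consecutive probes
.ar1_noise <- function(k, n, rho, sd) {
  e <- matrix(rnorm(k * n, sd = sd), k, n)
  if (k > 1L && rho > 0) {
    for (j in 2:k) e[j, ] <- rho * e[j - 1L, ] + sqrt(1 - rho^2) * e[j, ]
  }
  e
}

#' Simulate a twin cohort with known ground truth
#'
#' Counts follow `y[g,s] ~ NB(mu, phi_g)` with
#' `log mu = b_g + pair_effect + case * de_logfc * ln 2 + ln(L_s / 1e6)`,
#' where `b_g` is the baseline expression in logCPM units times `ln 2` (so the
#' natural-log link with a per-million offset makes `b_g / ln 2` the expected
#' logCPM). Both co-twins share the per-pair, per-gene effect. Methylation
#' M-values are AR(1)-correlated along probe position within each gene and
#' shifted by `meth_case_delta_m` in cases for differentially methylated
#' genes, then mapped to Beta = 2^M / (2^M + 1).
#'
#' @param config A [sim_config()].
#' @return A list of class `twin_cohort` with elements `counts` (integer
#'   matrix), `meth` (a `methylation_set`), `sheet` (sample sheet) and `truth`
#'   (ground-truth list: `de_genes` with true log2 fold changes, `dm_genes`,
#'   `linked_genes`, `dispersions`, `pair_effects`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  ## --- sample sheet -------------------------------------------------------
  groups <- rep(c("discordant", "concordant_case", "control"),
                c(config$n_pairs_discordant, config$n_pairs_concordant_case,
                  config$n_pairs_control))
  n_pairs <- length(groups)
  if (n_pairs == 0L) stop("at least one twin pair is required")
  pair_ids <- sprintf("P%02d", seq_len(n_pairs))
  # twin sex is a pair-level attribute; cohorts of this design are
  # predominantly male
  pair_sex <- ifelse(runif(n_pairs) < 0.8, "M", "F")
  rows <- lapply(seq_len(n_pairs), function(i) {
    case <- switch(groups[i],
                   discordant = sample(c(1L, 0L)),
                   concordant_case = c(1L, 1L),
                   control = c(0L, 0L))
    data.frame(sample_id = paste0(pair_ids[i], c("a", "b")),
               pair_id = pair_ids[i], group = groups[i], case = case,
               sex = pair_sex[i], stringsAsFactors = FALSE)
  })
  sheet <- do.call(rbind, rows)
  if (config$n_singletons > 0L) {
    sg <- sample(c("discordant", "concordant_case", "control"),
                 config$n_singletons, replace = TRUE)
    singles <- data.frame(
      sample_id = sprintf("S%02da", seq_len(config$n_singletons)),
      pair_id = sprintf("S%02d", seq_len(config$n_singletons)),
      group = sg,
      case = ifelse(sg == "concordant_case", 1L,
                    ifelse(sg == "control", 0L, rbinom(config$n_singletons, 1L, 0.5))),
      sex = ifelse(runif(config$n_singletons) < 0.8, "M", "F"),
      stringsAsFactors = FALSE)
    sheet <- rbind(sheet, singles)
  }
  n_samples <- nrow(sheet)

  ## --- expression ---------------------------------------------------------
  G <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(G))
  b_logcpm <- runif(G, config$baseline_logcpm_range[1L], config$baseline_logcpm_range[2L])
  phi <- rgamma(G, shape = config$dispersion_shape, rate = config$dispersion_rate)
  phi <- pmax(phi, 1e-4)
  de_idx <- sort(sample.int(G, config$n_de_genes))
  true_lfc <- numeric(G)
  true_lfc[de_idx] <- config$de_logfc

  all_pairs <- unique(sheet$pair_id)
  pair_eff <- matrix(rnorm(G * length(all_pairs), sd = config$pair_effect_sd * log(2)),
                     G, length(all_pairs), dimnames = list(gene_ids, all_pairs))
  lib <- round(runif(n_samples, config$library_size_range[1L], config$library_size_range[2L]))

  counts <- matrix(0L, G, n_samples, dimnames = list(gene_ids, sheet$sample_id))
  for (s in seq_len(n_samples)) {
    eta <- b_logcpm * log(2) +
      pair_eff[, sheet$pair_id[s]] +
      sheet$case[s] * true_lfc * log(2) +
      log(lib[s] / 1e6)
    counts[, s] <- as.integer(rnbinom(G, mu = exp(eta), size = 1 / phi))
  }

  ## --- methylation --------------------------------------------------------
  linked_idx <- sort(sample(de_idx, config$n_linked_genes))
  # differentially methylated genes: the linked genes plus an equal number of
  # expression-null genes, so methylation evidence alone does not imply DE
  non_de <- setdiff(seq_len(G), de_idx)
  dm_only <- sort(sample(non_de, min(config$n_linked_genes, length(non_de))))
  dm_idx <- sort(union(linked_idx, dm_only))

  k_probe <- rpois(G, config$n_probes_per_gene_mean)
  k_probe[dm_idx] <- pmax(k_probe[dm_idx], 1L)  # dm genes must be measurable
  has_probe <- which(k_probe > 0L)
  chroms <- paste0("chr", 1:22)
  manifest <- NULL
  beta_rows <- list()
  case_vec <- sheet$case
  dm_flag <- logical(G); dm_flag[dm_idx] <- TRUE
  for (gi in has_probe) {
    k <- k_probe[gi]
    chrom <- chroms[(gi - 1L) %% length(chroms) + 1L]
    start <- 1e5 * ((gi - 1L) %/% length(chroms) + 1L)
    pos <- start + (seq_len(k) - 1L) * config$probe_spacing_bp
    probe_id <- sprintf("%s_cg%02d", gene_ids[gi], seq_len(k))
    manifest <- rbind(manifest, data.frame(
      chrom = chrom, position = pos, probe_id = probe_id,
      gene_id = gene_ids[gi], stringsAsFactors = FALSE))
    mu_probe <- rnorm(k, 0, 1.5)  # probe baselines span methylated/unmethylated
    m <- mu_probe + .ar1_noise(k, n_samples, config$meth_spatial_rho, config$meth_noise_sd)
    if (dm_flag[gi]) {
      m <- m + config$meth_case_delta_m * matrix(case_vec, k, n_samples, byrow = TRUE)
    }
    rownames(m) <- probe_id
    beta_rows[[length(beta_rows) + 1L]] <- m
  }
  m_all <- do.call(rbind, beta_rows)
  beta <- m_to_beta(m_all)
  colnames(beta) <- sheet$sample_id
  meth <- suppressWarnings(methylation_set(beta, manifest))

  truth <- list(
    de_genes = data.frame(gene_id = gene_ids[de_idx], logfc = true_lfc[de_idx],
                          stringsAsFactors = FALSE),
    dm_genes = gene_ids[dm_idx],
    linked_genes = gene_ids[linked_idx],
    dispersions = setNames(phi, gene_ids),
    baseline_logcpm = setNames(b_logcpm, gene_ids),
    pair_effects = pair_eff)

  structure(list(counts = counts, meth = meth, sheet = sheet, truth = truth,
                 config = config),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat("twin_cohort:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      nrow(x$meth$beta), "CpG probes;",
      nrow(x$truth$de_genes), "true DE genes\n")
  invisible(x)
}

#' Write a simulated cohort to disk as plain-text fixtures
#'
#' Writes `counts.tsv`, `beta.tsv`, `manifest.tsv`, `sheet.tsv` and
#' `truth.json` into `dir_path`; the first four round-trip losslessly through
#' the package readers.
#'
#' @param cohort A `twin_cohort` from [simulate_cohort()].
#' @param dir_path Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_fixture <- function(cohort, dir_path) {
  stopifnot(inherits(cohort, "twin_cohort"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir_path, "counts.tsv"),
    beta = file.path(dir_path, "beta.tsv"),
    manifest = file.path(dir_path, "manifest.tsv"),
    sheet = file.path(dir_path, "sheet.tsv"),
    truth = file.path(dir_path, "truth.json"))
  write_counts(cohort$counts, paths[["counts"]])
  beta_df <- data.frame(probe_id = rownames(cohort$meth$beta), cohort$meth$beta,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write.table(beta_df, paths[["beta"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_table(cohort$meth$manifest, paths[["manifest"]])
  write_sample_sheet(cohort$sheet, paths[["sheet"]])
  truth <- cohort$truth
  truth$pair_effects <- NULL  # large and derivable from the seed
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
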