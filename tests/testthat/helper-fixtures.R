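# Small in-code fixtures shared across tests

# minimal valid sample sheet: n_disc discordant + n_ctrl control pairs
toy_sheet <- function(n_disc = 2, n_ctrl = 0, n_conc = 0) {
  groups <- rep(c("discordant", "concordant_case", "control"),
                c(n_disc, n_conc, n_ctrl))
  rows <- lapply(seq_along(groups), function(i) {
    case <- switch(groups[i], discordant = c(1L, 0L),
                   concordant_case = c(1L, 1L), control = c(0L, 0L))
    data.frame(sample_id = sprintf("P%02d%s", i, c("a", "b")),
               pair_id = sprintf("P%02d", i), group = groups[i],
               case = case, sex = "M", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# deterministic toy count matrix for a sheet
toy_counts <- function(sheet, n_genes = 100, seed = 99) {
  set.seed(seed)
  n <- nrow(sheet)
  m <- matrix(rnbinom(n_genes * n, mu = 50, size = 5), n_genes, n,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)), sheet$sample_id))
  storage.mode(m) <- "integer"
  m
}

# the three printed toy count fixtures used for NB-GLM oracle equivalence
# (8 samples: 4 pairs of a discordant design collapsed to intercept + case)
nb_toys <- list(
  list(y = c(12L, 30L, 7L, 21L, 45L, 18L, 3L, 26L),
       x = c(0, 1, 0, 1, 0, 1, 0, 1),
       off = log(c(1.8e6, 2.1e6, 1.6e6, 2.0e6, 2.2e6, 1.9e6, 1.5e6, 2.3e6) / 1e6),
       phi = 0.1),
  list(y = c(0L, 4L, 1L, 9L, 2L, 6L, 0L, 11L),
       x = c(0, 1, 0, 1, 0, 1, 0, 1),
       off = rep(0, 8),
       phi = 0.1),
  list(y = c(250L, 255L, 248L, 260L, 251L, 247L, 259L, 250L),
       x = NULL,  # intercept-only
       off = rep(log(2), 8),
       phi = 0.1))
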