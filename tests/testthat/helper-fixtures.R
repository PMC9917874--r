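# compact peptide-table constructor for unit tests
peptide_rows <- function(protein, ratios, subject = "S1", time = 4,
                         group = "control_diabetic", intensity = 1e6,
                         run = NULL) {
  n <- length(ratios)
  tibble::tibble(
    subject_id = subject,
    group = group,
    time_h = time,
    protein_id = protein,
    peptide_id = paste0(protein, "_pep", seq_len(n)),
    ratio_hl = ratios,
    intensity = rep_len(intensity, n),
    run_id = if (is.null(run)) paste0(subject, "_t", time) else run)
}

# peptide replicate cohort for noise-model calibration: known true ratios
# spread log-uniformly, replicate spread following SD(r) = sqrt(a^2 + b^2 r^2)
calibration_peptides <- function(seed, n_proteins = 4000, n_pep = 12,
                                 r_lo = 0.05, r_hi = 1.5,
                                 alpha = 0.02, beta = 0.1) {
  set.seed(seed)
  r_true <- exp(stats::runif(n_proteins, log(r_lo), log(r_hi)))
  sdr <- sqrt(alpha^2 + beta^2 * r_true^2)
  m <- rep(r_true, each = n_pep)
  s <- rep(sdr, each = n_pep)
  rat <- stats::rnorm(n_proteins * n_pep, m, s)
  while (any(rat < 0)) {
    i <- rat < 0
    rat[i] <- stats::rnorm(sum(i), m[i], s[i])
  }
  ids <- rep(sprintf("Q%04d", seq_len(n_proteins)), each = n_pep)
  tibble::tibble(
    subject_id = "S1", group = "control_diabetic", time_h = 4,
    protein_id = ids,
    peptide_id = paste0(ids, "_", seq_len(n_pep)),
    ratio_hl = rat, intensity = 1e6, run_id = "S1_t4")
}

# write a tibble to a temporary TSV and return the path
withr_local_tsv <- function(tbl) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  path
}

# noiseless ratio trajectory for a given half-life
ratio_at <- function(halflife_h, times_h) {
  exp(log(2) / halflife_h * times_h) - 1
}
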