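#' Configuration for a synthetic dynamic-SILAC cohort
#'
#' Bundles the generative parameters of [simulate_cohort()]. Defaults
#' emulate the study design the package targets: two groups (diabetic
#' controls vs nephropathic) of 5 subjects each, sampling times 4, 7.5 and
#' 24 h after the medium switch, protein half-lives log-uniform between 3
#' and 600 h, relative abundances log-uniform over four orders of
#' magnitude, 2-15 peptides per protein, and ratio noise following
#' `SD(r) = sqrt(alpha^2 + beta^2 r^2)` with (0.02, 0.1).
#'
#' @param n_subjects_per_group Subjects per group (default 5).
#' @param n_proteins Number of proteins (default 1000).
#' @param times_h Sampling times in hours (default `c(4, 7.5, 24)`).
#' @param halflife_range_h Log-uniform bounds of true half-life in hours
#'   (default `c(3, 600)`).
#' @param abundance_log10_range Log10 bounds of true abundance in arbitrary
#'   units (default `c(2, 6)`, i.e. four orders of magnitude).
#' @param peptides_per_protein Integer range of peptides per protein
#'   (default `c(2, 15)`).
#' @param noise_alpha,noise_beta Technical-noise constants (default 0.02,
#'   0.1).
#' @param between_subject_cv_pct Biological between-subject CV of the rate
#'   constant and the abundance, in percent (default 10; lognormal
#'   multipliers).
#' @param intensity_cv_pct Multiplicative measurement noise on peptide
#'   intensities, percent (default 20).
#' @param missing_rate Per (protein, subject, time) dropout probability
#'   (default 0.1).
#' @param force_incomplete_rate Fraction of (protein, subject) pairs whose
#'   latest time point is deliberately removed so they fail the
#'   time-coverage rule (default 0.05); gives filter tests known expected
#'   counts.
#' @param group_effect `NULL`, or a list with `proteins` (character ids)
#'   and `halflife_ratio` (> 0): members' half-lives are multiplied by the
#'   ratio in the nephropathic group.
#' @param seed Integer; fully determines the generated cohort.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects_per_group = 5,
                             n_proteins = 1000,
                             times_h = c(4, 7.5, 24),
                             halflife_range_h = c(3, 600),
                             abundance_log10_range = c(2, 6),
                             peptides_per_protein = c(2, 15),
                             noise_alpha = 0.02,
                             noise_beta = 0.1,
                             between_subject_cv_pct = 10,
                             intensity_cv_pct = 20,
                             missing_rate = 0.1,
                             force_incomplete_rate = 0.05,
                             group_effect = NULL,
                             seed = 1) {
  stopifnot(n_subjects_per_group >= 1, n_proteins >= 1,
            length(times_h) >= 1, all(times_h >= 0),
            halflife_range_h[1] > 0, diff(halflife_range_h) >= 0,
            peptides_per_protein[1] >= 1,
            noise_alpha >= 0, noise_beta >= 0,
            between_subject_cv_pct >= 0, intensity_cv_pct >= 0,
            missing_rate >= 0, missing_rate < 1,
            force_incomplete_rate >= 0, force_incomplete_rate < 1)
  if (!is.null(group_effect)) {
    stopifnot(is.list(group_effect),
              !is.null(group_effect$proteins),
              group_effect$halflife_ratio > 0)
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' Apply a group-specific half-life shift to the ground truth
#'
#' Multiplies the true half-life (divides the rate constant) of the listed
#' proteins in the nephropathic group by `halflife_ratio`. Applying the
#' operation twice composes multiplicatively.
#'
#' @param truth Ground-truth tibble from [simulate_cohort()].
#' @param proteins Character ids of affected proteins; all must exist.
#' @param halflife_ratio Positive multiplier of the half-life (e.g. 1.23
#'   for a 23% longer half-life in the case group).
#' @return The modified truth tibble, with `effect_member` set.
#' @export
inject_group_effect <- function(truth, proteins, halflife_ratio) {
  stopifnot(halflife_ratio > 0)
  unknown <- setdiff(proteins, unique(truth$protein_id))
  if (length(unknown) > 0) {
    stop("unknown protein id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  hit <- truth$protein_id %in% proteins & truth$group == "nephropathic"
  truth$k_true[hit] <- truth$k_true[hit] / halflife_ratio
  truth$half_life_true_h[hit] <- log(2) / truth$k_true[hit]
  truth$effect_member[truth$protein_id %in% proteins] <- TRUE
  truth
}

# truncated-at-zero normal via resampling; sd may be 0 (degenerate)
rtrunc_norm0 <- function(mean, sd) {
  x <- stats::rnorm(length(mean), mean, sd)
  bad <- which(x < 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Simulate a peptide-level dynamic-SILAC cohort with known ground truth
#'
#' Generates a full synthetic cohort under the package's kinetic and noise
#' assumptions. Per protein, a base rate constant is drawn from the
#' log-uniform half-life distribution and an abundance from the log-uniform
#' abundance distribution; per subject, both receive lognormal biological
#' variation. Label incorporation follows first-order decay of the light
#' pool at steady state, so the true ratio at time t is
#' `r(t) = exp(k t) - 1` and the heavy and light pools always sum to the
#' (constant) total. Observed peptide ratios are drawn from a normal
#' distribution centred on r(t) with SD from the technical-noise law,
#' truncated at zero by resampling. Peptide intensities are the subject's
#' true abundance times a peptide-specific lognormal ionization factor
#' (fixed across time points, so abundance is time-stationary) times
#' multiplicative measurement noise.
#'
#' Missingness is completely at random per (protein, subject, time); an
#' additional mechanism removes the latest time point for a known fraction
#' of (protein, subject) pairs so the time-coverage filter has a
#' ground-truth exclusion set.
#'
#' @param config A [synthetic_config()].
#' @return A list with `measurements` (canonical peptide tibble ready for
#'   [aggregate_protein_ratios()]) and `truth` (per protein and subject:
#'   `k_true`, `half_life_true_h`, `abundance_true`, `effect_member`,
#'   `forced_incomplete`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_prot <- cfg$n_proteins
  nspg <- cfg$n_subjects_per_group
  protein_id <- sprintf("P%04d", seq_len(n_prot))
  subjects <- tibble::tibble(
    subject_id = c(sprintf("D%02d", seq_len(nspg)),
                   sprintf("N%02d", seq_len(nspg))),
    group = rep(c("control_diabetic", "nephropathic"), each = nspg))

  # per-protein truth
  lhl <- stats::runif(n_prot, log(cfg$halflife_range_h[1]),
                      log(cfg$halflife_range_h[2]))
  base_k <- log(2) / exp(lhl)
  base_abund <- 10^stats::runif(n_prot, cfg$abundance_log10_range[1],
                                cfg$abundance_log10_range[2])
  n_pep <- sample(seq(cfg$peptides_per_protein[1],
                      cfg$peptides_per_protein[2]),
                  n_prot, replace = TRUE)

  # fixed peptide ionization factors (shared across subjects and times)
  pep_protein <- rep(protein_id, n_pep)
  peptides <- tibble::tibble(
    protein_id = pep_protein,
    peptide_id = paste0(pep_protein, "_pep", unlist(lapply(n_pep, seq_len))),
    ion_factor = stats::rlnorm(sum(n_pep), meanlog = 0, sdlog = 1))

  cv <- cfg$between_subject_cv_pct / 100
  sdlog <- sqrt(log(1 + cv^2))
  n_ps <- n_prot * nrow(subjects)
  truth <- tidyr::expand_grid(
    tibble::tibble(protein_id = protein_id, base_k = base_k,
                   base_abund = base_abund),
    subjects) |>
    dplyr::mutate(
      k_true = .data$base_k *
        stats::rlnorm(n_ps, meanlog = -sdlog^2 / 2, sdlog = sdlog),
      abundance_true = .data$base_abund *
        stats::rlnorm(n_ps, meanlog = -sdlog^2 / 2, sdlog = sdlog),
      half_life_true_h = log(2) / .data$k_true,
      effect_member = FALSE,
      forced_incomplete = stats::runif(n_ps) < cfg$force_incomplete_rate) |>
    dplyr::select("protein_id", "subject_id", "group", "k_true",
                  "half_life_true_h", "abundance_true", "effect_member",
                  "forced_incomplete")

  if (!is.null(cfg$group_effect)) {
    truth <- inject_group_effect(truth, cfg$group_effect$proteins,
                                 cfg$group_effect$halflife_ratio)
  }

  # (protein, subject, time) grid with dropout; forced pairs lose the
  # latest time point outright
  t_max <- max(cfg$times_h)
  grid <- tidyr::expand_grid(truth, time_h = cfg$times_h) |>
    dplyr::filter(!(.data$forced_incomplete & .data$time_h == t_max)) |>
    dplyr::filter(stats::runif(dplyr::n()) >= cfg$missing_rate)

  obs <- grid |>
    dplyr::inner_join(peptides, by = "protein_id",
                      relationship = "many-to-many") |>
    dplyr::mutate(
      r_true = exp(.data$k_true * .data$time_h) - 1,
      sd_r = sqrt(cfg$noise_alpha^2 + cfg$noise_beta^2 * .data$r_true^2),
      ratio_hl = rtrunc_norm0(.data$r_true, .data$sd_r),
      intensity = .data$abundance_true * .data$ion_factor *
        stats::rlnorm(dplyr::n(),
                      sdlog = sqrt(log(1 + (cfg$intensity_cv_pct / 100)^2))),
      run_id = paste0(.data$subject_id, "_t", .data$time_h))

  measurements <- obs |>
    dplyr::select("subject_id", "group", "time_h", "protein_id",
                  "peptide_id", "ratio_hl", "intensity", "run_id")

  list(measurements = measurements, truth = truth)
}
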