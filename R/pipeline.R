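#' Configuration of the end-to-end turnover pipeline
#'
#' Collects the thresholds and options of [run_pipeline()] with the
#' defaults the package uses throughout: measurement and fit CV cut-offs
#' at 50%, the mandatory 24 h time point plus at least one earlier one,
#' at least 2 subjects per protein (and per group for comparisons), and
#' the fixed technical-noise constants (0.02, 0.1) unless `fit_noise` is
#' requested.
#'
#' @param times_h Design time points, ascending (default `c(4, 7.5, 24)`).
#' @param required_time Mandatory time point for the kinetic fit (default
#'   24; must be one of `times_h`).
#' @param max_measurement_cv Across-peptide CV threshold, percent
#'   (default 50).
#' @param max_fit_cv Estimate-CV threshold, percent (default 50).
#' @param min_subjects Minimum subjects per protein for cross-subject
#'   summaries and per group for comparisons (default 2).
#' @param noise A [noise_model()] used when `fit_noise = FALSE`.
#' @param fit_noise If `TRUE`, calibrate (alpha, beta) from the data by
#'   [bin_ratios()] + [fit_noise_model()] instead of using `noise`.
#' @param bin_size,min_bin_count Binning parameters for noise calibration.
#' @param halflife_edges,abundance_edges Interval edges for the binning
#'   summaries.
#' @param group_a,group_b Group labels (reference and case).
#' @param exclude_proteins Optional character vector of contaminant ids
#'   dropped before any analysis (e.g. keratins).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(times_h = c(4, 7.5, 24),
                            required_time = 24,
                            max_measurement_cv = 50,
                            max_fit_cv = 50,
                            min_subjects = 2,
                            noise = noise_model(),
                            fit_noise = FALSE,
                            bin_size = 0.05,
                            min_bin_count = 10,
                            halflife_edges = c(20, 30, 40, 50, 60, 70, 80, 90),
                            abundance_edges = c(5, 6, 6.5, 7, 7.5, 8, 9),
                            group_a = "control_diabetic",
                            group_b = "nephropathic",
                            exclude_proteins = NULL) {
  stopifnot(is.unsorted(times_h) == FALSE, required_time %in% times_h,
            max_measurement_cv > 0, max_fit_cv >= 0, min_subjects >= 1,
            inherits(noise, "noise_model"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full turnover analysis pipeline
#'
#' Executes the stages in their canonical order: peptide-to-protein
#' aggregation, measurement-CV filter, noise-model selection (fixed or
#' fitted), time-coverage filter, weighted kinetic fit, fit-CV filter,
#' abundance estimation with steady-state averaging and diagnostic,
#' cross-subject summaries and two-group comparisons, and interval
#' binning. A manifest accounts for every row entering and leaving each
#' filter; identical input and configuration reproduce identical outputs.
#'
#' @param measurements Canonical peptide measurement tibble (from
#'   [read_peptide_table()] or [simulate_cohort()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage table is
#'   written there as TSV together with the manifest and the noise-model
#'   parameters.
#' @return A list: `protein_ratios`, `ratios_cv_filtered`, `noise`,
#'   `ratios_covered`, `fits`, `fits_reliable`, `abundance_by_time`,
#'   `abundance`, `steady_state`, `halflife_summary`, `abundance_summary`,
#'   `comparison_halflife`, `comparison_abundance`, `halflife_bins`,
#'   `abundance_bins`, `manifest`.
#' @export
run_pipeline <- function(measurements, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list()
  note <- function(stage, n_in, n_out) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out,
      n_excluded = n_in - n_out)
  }

  if (!is.null(config$exclude_proteins)) {
    n0 <- nrow(measurements)
    measurements <- dplyr::filter(
      measurements, !.data$protein_id %in% config$exclude_proteins)
    note("contaminant_filter", n0, nrow(measurements))
  }

  pr <- aggregate_protein_ratios(measurements)
  note("aggregate", nrow(measurements), nrow(pr))

  pr_cv <- filter_measurement_cv(pr, config$max_measurement_cv)
  note("measurement_cv_filter", nrow(pr), nrow(pr_cv))

  noise <- if (config$fit_noise) {
    bins <- bin_ratios(pr_cv, bin_size = config$bin_size,
                       min_count = config$min_bin_count)
    fit_noise_model(bins, min_count = config$min_bin_count)
  } else {
    config$noise
  }

  pr_cov <- filter_time_coverage(pr_cv, required_time = config$required_time)
  note("time_coverage_filter", nrow(pr_cv), nrow(pr_cov))

  fits <- fit_turnover(pr_cov, noise)
  note("kinetic_fit", nrow(pr_cov), nrow(fits))

  fits_ok <- filter_fit_cv(fits, config$max_fit_cv)
  note("fit_cv_filter", nrow(fits), nrow(fits_ok))

  abund_t <- protein_abundance_by_time(measurements)
  abund <- average_steady_state(abund_t)
  steady <- steady_state_check(measurements)

  hl_sum <- summarize_protein(fits_ok, .data$half_life_h,
                              min_subjects = config$min_subjects)
  ab_sum <- summarize_protein(abund, .data$log2_abundance,
                              min_subjects = config$min_subjects)

  cmp_hl <- compare_groups(fits_ok, .data$half_life_h,
                           variable = "half_life",
                           group_a = config$group_a, group_b = config$group_b,
                           min_subjects = config$min_subjects)
  cmp_ab <- compare_groups(abund, .data$mean_abundance,
                           variable = "abundance",
                           group_a = config$group_a, group_b = config$group_b,
                           min_subjects = config$min_subjects)

  hl_bins <- bin_by_halflife(hl_sum, .data$mean, edges = config$halflife_edges)
  ab_bins <- bin_by_abundance(ab_sum, .data$mean, edges = config$abundance_edges)

  manifest <- dplyr::bind_rows(manifest)
  out <- list(protein_ratios = pr,
              ratios_cv_filtered = pr_cv,
              noise = noise,
              ratios_covered = pr_cov,
              fits = fits,
              fits_reliable = fits_ok,
              abundance_by_time = abund_t,
              abundance = abund,
              steady_state = steady,
              halflife_summary = hl_sum,
              abundance_summary = ab_sum,
              comparison_halflife = cmp_hl,
              comparison_abundance = cmp_ab,
              halflife_bins = hl_bins,
              abundance_bins = ab_bins,
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tables <- out[vapply(out, is.data.frame, logical(1))]
    for (nm in names(tables)) {
      readr::write_tsv(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
    write_noise_model(noise, file.path(out_dir, "noise_model.txt"))
  }
  out
}
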