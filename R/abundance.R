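#' Per-run relative protein abundance
#'
#' For one LC-MS/MS run (or a set of runs merged at the peptide level), the
#' relative abundance of a protein is the sum of its peptide peak
#' intensities divided by the number of distinct observed peptides, then
#' normalised by the total intensity sum of the run:
#' \deqn{A_p = \frac{\sum_{i \in p} I_i / n_p}{\sum_j I_j}.}
#' The within-run normalisation makes abundances invariant to a global
#' rescaling of the run; proteins absent from the run are omitted, never
#' zero-filled.
#'
#' @param measurements Peptide measurements of a single run (one merged
#'   sample); must carry `protein_id`, `peptide_id`, `intensity`.
#' @return A tibble per protein: `protein_id`, `n_obs_peptides`,
#'   `abundance`.
#' @export
compute_run_abundance <- function(measurements) {
  total <- sum(measurements$intensity)
  if (!isTRUE(total > 0)) stop("total run intensity is zero", call. = FALSE)
  measurements |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_obs_peptides = dplyr::n_distinct(.data$peptide_id),
      abundance = (sum(.data$intensity) / dplyr::n_distinct(.data$peptide_id)) / total,
      .groups = "drop")
}

#' Relative protein abundance per subject and time point
#'
#' Applies the per-run abundance formula to each (subject, time point)
#' sample. When a sample was acquired in several runs (gel bands, repeated
#' injections), peptide intensities are first summed across those runs and
#' the normalising total is the merged total.
#'
#' @param measurements Peptide measurement tibble for a whole cohort.
#' @return A tibble: `protein_id`, `subject_id`, `group`, `time_h`,
#'   `n_obs_peptides`, `abundance`.
#' @export
protein_abundance_by_time <- function(measurements) {
  merged <- measurements |>
    dplyr::group_by(.data$subject_id, .data$time_h, .data$protein_id,
                    .data$peptide_id) |>
    dplyr::summarise(group = dplyr::first(.data$group),
                     intensity = sum(.data$intensity),
                     .groups = "drop")
  merged |>
    dplyr::group_by(.data$subject_id, .data$time_h) |>
    dplyr::mutate(.total = sum(.data$intensity)) |>
    dplyr::group_by(.data$subject_id, .data$time_h, .data$protein_id) |>
    dplyr::summarise(
      group = dplyr::first(.data$group),
      n_obs_peptides = dplyr::n_distinct(.data$peptide_id),
      abundance = (sum(.data$intensity) / dplyr::n_distinct(.data$peptide_id)) /
        dplyr::first(.data$.total),
      .groups = "drop") |>
    dplyr::relocate("protein_id")
}

#' Steady-state averaging of abundance across time points
#'
#' Under the steady-state assumption the true abundance does not change
#' over the labelling time course, so the per-time estimates are averaged
#' (arithmetic mean over the time points actually observed) and reported
#' with their log2.
#'
#' @param abundances Output of [protein_abundance_by_time()].
#' @return A tibble per (protein_id, subject_id): `group`, `n_times`,
#'   `mean_abundance`, `log2_abundance`.
#' @export
average_steady_state <- function(abundances) {
  abundances |>
    dplyr::group_by(.data$protein_id, .data$subject_id) |>
    dplyr::summarise(
      group = dplyr::first(.data$group),
      n_times = dplyr::n_distinct(.data$time_h),
      mean_abundance = mean(.data$abundance),
      .groups = "drop") |>
    dplyr::mutate(log2_abundance = log2(.data$mean_abundance))
}

#' Steady-state diagnostic: temporal vs technical variance
#'
#' Checks the steady-state premise on the data themselves: per (protein,
#' subject), the variance of the protein's relative abundance across time
#' points is compared with the technical variance, measured as the median
#' across time points of the variance of peptide-level relative abundances
#' (peptide intensity over run total) within the same sample. If abundance
#' is stationary, temporal spread should not exceed what peptide-to-peptide
#' disagreement already explains.
#'
#' @param measurements Peptide measurement tibble.
#' @return A tibble per (protein_id, subject_id): `n_times`,
#'   `temporal_variance`, `technical_variance`, `ratio`,
#'   `temporal_exceeds` (flag), plus attribute `"fraction_within"` — the
#'   fraction of rows with temporal variance at or below technical.
#' @export
steady_state_check <- function(measurements) {
  per_pep <- measurements |>
    dplyr::group_by(.data$subject_id, .data$time_h, .data$protein_id,
                    .data$peptide_id) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    dplyr::group_by(.data$subject_id, .data$time_h) |>
    dplyr::mutate(rel_int = .data$intensity / sum(.data$intensity)) |>
    dplyr::ungroup()

  tech <- per_pep |>
    dplyr::group_by(.data$protein_id, .data$subject_id, .data$time_h) |>
    dplyr::summarise(n_pep = dplyr::n(),
                     pep_var = stats::var(.data$rel_int),
                     .groups = "drop") |>
    dplyr::filter(.data$n_pep >= 2) |>
    dplyr::group_by(.data$protein_id, .data$subject_id) |>
    dplyr::summarise(technical_variance = stats::median(.data$pep_var),
                     .groups = "drop")

  temporal <- protein_abundance_by_time(measurements) |>
    dplyr::group_by(.data$protein_id, .data$subject_id) |>
    dplyr::summarise(n_times = dplyr::n(),
                     temporal_variance = stats::var(.data$abundance),
                     .groups = "drop") |>
    dplyr::filter(.data$n_times >= 2)

  out <- dplyr::inner_join(temporal, tech,
                           by = c("protein_id", "subject_id")) |>
    dplyr::mutate(ratio = .data$temporal_variance / .data$technical_variance,
                  temporal_exceeds = .data$temporal_variance > .data$technical_variance)
  attr(out, "fraction_within") <- if (nrow(out) > 0) mean(!out$temporal_exceeds) else NA_real_
  out
}
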