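#' Filter proteins by time-point coverage
#'
#' The degradation rate is only estimated for (protein, subject) pairs
#' quantified at the latest design time point (24 h by default) and at
#' least one earlier time point: the late point anchors the fit for
#' long-lived proteins whose ratio grows slowly, while a second point
#' constrains the slope. Pairs failing the rule are removed; excluded
#' (protein, subject) pairs are attached as the `"exclusion_report"`
#' attribute.
#'
#' @param protein_ratios Protein-level ratio tibble (aggregated and
#'   CV-filtered).
#' @param required_time The mandatory time point in hours (default 24).
#' @param min_other Minimum number of other time points required (default 1).
#' @return The retained rows, with an `"exclusion_report"` attribute.
#' @export
filter_time_coverage <- function(protein_ratios, required_time = 24,
                                 min_other = 1) {
  cov <- protein_ratios |>
    dplyr::group_by(.data$protein_id, .data$subject_id) |>
    dplyr::summarise(
      has_required = any(.data$time_h == required_time),
      n_other = dplyr::n_distinct(.data$time_h[.data$time_h != required_time]),
      .groups = "drop") |>
    dplyr::mutate(keep = .data$has_required & .data$n_other >= min_other)

  out <- protein_ratios |>
    dplyr::inner_join(dplyr::filter(cov, .data$keep) |>
                        dplyr::select("protein_id", "subject_id"),
                      by = c("protein_id", "subject_id"))
  attr(out, "exclusion_report") <- cov |>
    dplyr::filter(!.data$keep) |>
    dplyr::select("protein_id", "subject_id", "has_required", "n_other")
  out
}

#' Weighted least-squares fit of the degradation rate constant
#'
#' Fits the log-linearised label-incorporation model
#' \deqn{\ln(r + 1) = k t}
#' through the origin by weighted least squares. Under first-order decay of
#' the pre-existing (light) pool at steady state, the heavy/light ratio is
#' `r(t) = exp(k t) - 1`, so `ln(r + 1)` is exactly linear in time with no
#' intercept (the label fraction is zero at t = 0). The closed-form
#' estimator is
#' \deqn{\hat k = \sum_i w_i t_i y_i / \sum_i w_i t_i^2,\qquad
#'       se(\hat k) = 1/\sqrt{\sum_i w_i t_i^2},}
#' with y = ln(r + 1) and weights the absolute inverse variances of y
#' obtained from the technical-variability model by the delta method:
#' `Var(y) = SD(r)^2 / (1 + r)^2`, hence `w = (1 + r)^2 / SD(r)^2`.
#'
#' @param time_h Numeric vector of time points (hours), at least one
#'   non-zero.
#' @param r Protein-level H/L ratios at those times (non-negative).
#' @param noise A [noise_model()] supplying SD(r).
#' @return A one-row tibble: `k`, `se_k`, `cv_k` (percent, `100 se/|k|`),
#'   `half_life_h` (`ln 2 / k`, `NA` when `k <= 0`), `n_points`, `valid`
#'   (`k > 0`), `reliable` (`valid` and `cv_k <= 50`).
#' @export
fit_k_wls <- function(time_h, r, noise) {
  stopifnot(length(time_h) == length(r), length(r) >= 1)
  if (all(time_h == 0)) stop("all time points are zero; k is not identifiable", call. = FALSE)
  sd_r <- predict_sd(noise, r)
  w <- (1 + r)^2 / sd_r^2
  if (any(!is.finite(w) | w <= 0)) {
    stop("non-finite or non-positive weight at point ",
         which(!is.finite(w) | w <= 0)[1], call. = FALSE)
  }
  y <- log(r + 1)
  swt2 <- sum(w * time_h^2)
  k <- sum(w * time_h * y) / swt2
  se <- sqrt(1 / swt2)
  cv <- 100 * se / abs(k)
  tibble::tibble(
    k = k, se_k = se, cv_k = cv,
    half_life_h = ifelse(k > 0, log(2) / k, NA_real_),
    n_points = length(r),
    valid = k > 0,
    reliable = k > 0 & cv <= 50)
}

#' Half-life from a degradation rate constant
#'
#' `T_1/2 = ln 2 / k`: the time for the pre-existing pool to halve in the
#' absence of synthesis.
#'
#' @param k Positive rate constant (per hour).
#' @return Half-life in hours.
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop("half-life requires k > 0", call. = FALSE)
  log(2) / k
}

#' Fit turnover kinetics for every (protein, subject) pair
#'
#' Vectorised batch version of [fit_k_wls()]: one weighted regression
#' through the origin per (protein, subject), using the technical noise
#' model for the weights. Estimates with `k <= 0` (possible under noise for
#' very slow proteins) are marked invalid rather than clipped and carry no
#' half-life.
#'
#' @param protein_ratios Protein-level ratio tibble that passed
#'   [filter_time_coverage()].
#' @param noise A [noise_model()].
#' @return A tibble with one row per (protein_id, subject_id): `group`,
#'   `k`, `se_k`, `cv_k`, `half_life_h`, `n_points`, `valid`, `reliable`.
#' @export
fit_turnover <- function(protein_ratios, noise = noise_model()) {
  stopifnot(inherits(noise, "noise_model"))
  if (nrow(protein_ratios) == 0) {
    return(tibble::tibble(protein_id = character(), subject_id = character(),
                          group = character(), k = numeric(), se_k = numeric(),
                          cv_k = numeric(), half_life_h = numeric(),
                          n_points = integer(), valid = logical(),
                          reliable = logical()))
  }
  protein_ratios |>
    dplyr::mutate(
      .sd = predict_sd(noise, .data$r),
      .y = log(.data$r + 1),
      .w = (1 + .data$r)^2 / .data$.sd^2) |>
    dplyr::group_by(.data$protein_id, .data$subject_id) |>
    dplyr::summarise(
      group = dplyr::first(.data$group),
      .swt2 = sum(.data$.w * .data$time_h^2),
      k = sum(.data$.w * .data$time_h * .data$.y) / .data$.swt2,
      se_k = sqrt(1 / .data$.swt2),
      n_points = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(
      cv_k = 100 * .data$se_k / abs(.data$k),
      half_life_h = dplyr::if_else(.data$k > 0, log(2) / .data$k, NA_real_),
      valid = .data$k > 0,
      reliable = .data$valid & .data$cv_k <= 50) |>
    dplyr::select("protein_id", "subject_id", "group", "k", "se_k", "cv_k",
                  "half_life_h", "n_points", "valid", "reliable")
}

#' Filter turnover fits by the CV of the rate estimate
#'
#' Fits whose estimate CV (`100 * se_k / |k|`) exceeds `max_cv_pct` — or
#' whose rate is non-positive — are considered unreliable and removed from
#' downstream cohort statistics. A summary attached as the `"cv_summary"`
#' attribute reports the retained fraction and, as a precision diagnostic,
#' the fraction of valid fits with CV below 15%.
#'
#' @param fits Output of [fit_turnover()].
#' @param max_cv_pct Threshold in percent (default 50).
#' @return Reliable fits, with a `"cv_summary"` attribute.
#' @export
filter_fit_cv <- function(fits, max_cv_pct = 50) {
  keep <- fits$valid & fits$cv_k <= max_cv_pct
  out <- fits[keep, , drop = FALSE]
  n_valid <- sum(fits$valid)
  attr(out, "cv_summary") <- tibble::tibble(
    n_fits = nrow(fits),
    n_reliable = sum(keep),
    frac_reliable = ifelse(nrow(fits) > 0, mean(keep), NA_real_),
    frac_cv_below_15 = ifelse(n_valid > 0,
                              sum(fits$valid & fits$cv_k < 15) / n_valid,
                              NA_real_))
  out
}
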