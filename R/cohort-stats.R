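#' Cross-subject per-protein summaries
#'
#' Averages a per-subject quantity (half-life or abundance) across
#' subjects, keeping only proteins estimated in at least `min_subjects`
#' subjects; the cross-subject mean and sample SD are reported.
#'
#' @param x Tibble with `protein_id`, `subject_id` and the value column.
#' @param value Column to summarise (tidy-select, unquoted).
#' @param min_subjects Minimum subjects per protein (default 2).
#' @return A tibble per protein: `n_subjects`, `mean`, `sd`.
#' @export
summarize_protein <- function(x, value, min_subjects = 2) {
  x |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_subjects = dplyr::n_distinct(.data$subject_id),
      mean = mean({{ value }}),
      sd = stats::sd({{ value }}),
      .groups = "drop") |>
    dplyr::filter(.data$n_subjects >= min_subjects)
}

# pooled-variance two-sample t-test that tolerates degenerate inputs
pooled_t_p <- function(a, b) {
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    return(list(p = if (mean(a) == mean(b)) 1 else .Machine$double.xmin,
                degenerate = mean(a) != mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(p = tt$p.value, degenerate = FALSE)
}

#' Two-group comparison of a per-subject protein quantity
#'
#' For every protein with at least `min_subjects` values in each group,
#' performs a two-tailed pooled-variance (Student) unpaired t-test between
#' the two groups, flags normality of the pooled within-group residuals by
#' a Shapiro-Wilk test at the 0.05 level, and reports Benjamini-Hochberg
#' adjusted p-values across all tested proteins alongside the raw ones.
#' For `variable = "abundance"` a signed fold change of group means is
#' added: ratios of at least 1 are kept as-is, ratios below 1 are reported
#' as the negative reciprocal (so a negative sign means lower in group B).
#'
#' Proteins with fewer than `min_subjects` values in either group are
#' returned in the `"skipped"` attribute with the reason, not tested.
#'
#' @param x Tibble with `protein_id`, `subject_id`, `group` and the value
#'   column.
#' @param value Value column (tidy-select, unquoted).
#' @param variable `"half_life"` or `"abundance"`; governs the fold-change
#'   column.
#' @param group_a,group_b The two group labels; defaults are the reference
#'   (diabetic control) and case (nephropathic) labels. Fold change is B
#'   over A.
#' @param min_subjects Minimum per-group values (default 2).
#' @return A tibble per tested protein: `variable`, `mean_a`, `sd_a`,
#'   `n_a`, `mean_b`, `sd_b`, `n_b`, `p_value`, `fdr_bh`, `fold_change`
#'   (`NA` for half-life), `normality_ok`, `degenerate`.
#' @export
compare_groups <- function(x, value, variable = c("half_life", "abundance"),
                           group_a = "control_diabetic",
                           group_b = "nephropathic",
                           min_subjects = 2) {
  variable <- match.arg(variable)
  vals <- x |>
    dplyr::filter(.data$group %in% c(group_a, group_b)) |>
    dplyr::mutate(.value = {{ value }})

  counts <- vals |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(n_a = sum(.data$group == group_a),
                     n_b = sum(.data$group == group_b),
                     .groups = "drop")
  skipped <- counts |>
    dplyr::filter(.data$n_a < min_subjects | .data$n_b < min_subjects) |>
    dplyr::mutate(reason = "insufficient subjects")

  tested_ids <- setdiff(counts$protein_id, skipped$protein_id)
  out <- vals |>
    dplyr::filter(.data$protein_id %in% tested_ids) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(d, key) {
      a <- d$.value[d$group == group_a]
      b <- d$.value[d$group == group_b]
      if (length(a) < min_subjects || length(b) < min_subjects) {
        # schema-only call on an empty partition
        return(tibble::tibble(
          variable = character(), mean_a = numeric(), sd_a = numeric(),
          n_a = integer(), mean_b = numeric(), sd_b = numeric(),
          n_b = integer(), p_value = numeric(), fold_change = numeric(),
          normality_ok = logical(), degenerate = logical()))
      }
      tt <- pooled_t_p(a, b)
      resid <- c(a - mean(a), b - mean(b))
      norm_ok <- tryCatch(
        stats::shapiro.test(resid)$p.value >= 0.05,
        error = function(e) NA)
      fc <- if (variable == "abundance") {
        ratio <- mean(b) / mean(a)
        if (ratio >= 1) ratio else -1 / ratio
      } else {
        NA_real_
      }
      tibble::tibble(
        variable = variable,
        mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
        mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
        p_value = tt$p, fold_change = fc,
        normality_ok = norm_ok, degenerate = tt$degenerate)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(fdr_bh = stats::p.adjust(.data$p_value, method = "BH"),
                  .after = "p_value")
  attr(out, "skipped") <- skipped
  out
}

.halflife_edges <- c(20, 30, 40, 50, 60, 70, 80, 90)
.abundance_edges <- c(5.0, 6.0, 6.5, 7.0, 7.5, 8.0, 9.0)

# left-closed interval labelling over open-ended edges
interval_label <- function(x, edges) {
  labs <- c(paste0("<", edges[1]),
            paste0("[", utils::head(edges, -1), ",", edges[-1], ")"),
            paste0(">=", edges[length(edges)]))
  idx <- findInterval(x, edges) + 1L  # left-closed: x == edge goes right
  factor(labs[idx], levels = labs)
}

#' Group proteins into half-life intervals
#'
#' Assigns each protein's mean half-life to one of the intervals defined by
#' `edges` (left-closed; default nine bins `<20`, `[20,30)`, ..., `>=90`
#' hours). Non-positive half-lives are excluded and flagged in the
#' `"excluded"` attribute. Interval membership lists feed external
#' enrichment tools.
#'
#' @param x Tibble with `protein_id` and the half-life column.
#' @param value Half-life column in hours (tidy-select, unquoted).
#' @param edges Increasing interior bin edges (default
#'   `c(20,30,40,50,60,70,80,90)`).
#' @return `x` with a `bin` factor column, plus a `"bin_counts"` attribute
#'   (counts per interval, including empty ones).
#' @export
bin_by_halflife <- function(x, value, edges = .halflife_edges) {
  v <- dplyr::pull(x, {{ value }})
  bad <- !is.na(v) & v <= 0
  out <- x[!bad, , drop = FALSE]
  out$bin <- interval_label(v[!bad], edges)
  attr(out, "excluded") <- x[bad, , drop = FALSE]
  attr(out, "bin_counts") <- out |> dplyr::count(.data$bin, .drop = FALSE)
  out
}

#' Group proteins into log2-abundance intervals
#'
#' As [bin_by_halflife()] but on log2 relative abundance with default eight
#' bins `<5.0`, `[5.0,6.0)`, `[6.0,6.5)`, ..., `>=9.0`.
#'
#' @param x Tibble with `protein_id` and the log2 abundance column.
#' @param value Log2 abundance column (tidy-select, unquoted).
#' @param edges Increasing interior bin edges (default
#'   `c(5,6,6.5,7,7.5,8,9)`).
#' @return `x` with a `bin` factor column and a `"bin_counts"` attribute.
#' @export
bin_by_abundance <- function(x, value, edges = .abundance_edges) {
  v <- dplyr::pull(x, {{ value }})
  out <- x
  out$bin <- interval_label(v, edges)
  attr(out, "bin_counts") <- out |> dplyr::count(.data$bin, .drop = FALSE)
  out
}

#' Classify proteins into turnover-abundance quadrants
#'
#' Splits the (abundance, turnover-rate) plane into four quadrants at the
#' supplied thresholds: slow-turnover/high-abundance ("red"), fast/high
#' ("blue"), fast/low ("green") and slow/low ("pink"). Values exactly at a
#' threshold fall on the "high" side. Rows missing either coordinate are
#' labelled `NA` (unclassified).
#'
#' @param x Tibble with abundance and rate columns.
#' @param abundance,k The two coordinate columns (tidy-select, unquoted);
#'   abundance on whatever scale the thresholds are expressed in.
#' @param k_threshold,abundance_threshold Numeric cut-offs separating
#'   "high" from "low"; no universal defaults exist, so both must be
#'   chosen to fit the dataset (e.g. medians).
#' @return `x` with a `quadrant` factor column (levels `low-k/high-A`,
#'   `high-k/high-A`, `high-k/low-A`, `low-k/low-A`).
#' @export
quadrant_classify <- function(x, abundance, k, k_threshold,
                              abundance_threshold) {
  a <- dplyr::pull(x, {{ abundance }})
  kk <- dplyr::pull(x, {{ k }})
  high_a <- a >= abundance_threshold
  high_k <- kk >= k_threshold
  lab <- dplyr::case_when(
    is.na(a) | is.na(kk) ~ NA_character_,
    !high_k & high_a ~ "low-k/high-A",
    high_k & high_a ~ "high-k/high-A",
    high_k & !high_a ~ "high-k/low-A",
    TRUE ~ "low-k/low-A")
  x$quadrant <- factor(lab, levels = c("low-k/high-A", "high-k/high-A",
                                       "high-k/low-A", "low-k/low-A"))
  x
}

# run code with a temporarily-seeded RNG, restoring state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Half-life coherence of a macromolecular complex vs random protein sets
#'
#' Tests whether subunits of a complex have more similar half-lives than
#' chance by comparing the dispersion (SD and IQR) of the members'
#' half-lives with that of `n_populations` random protein sets of the same
#' size drawn without replacement from the full half-life table. The
#' fraction of random populations with a larger SD quantifies coherence
#' (1 = tighter than every random draw). The draw is fully determined by
#' `seed`.
#'
#' @param members Character vector of member protein ids (at least 3 must
#'   be present in `halflife_table`).
#' @param halflife_table Per-protein table with `protein_id` and `mean`
#'   half-life columns (e.g. from [summarize_protein()]).
#' @param n_populations Number of random same-size sets (default 10).
#' @param seed Integer seed controlling the draws.
#' @return A list: `complex` (tibble with n, sd, iqr), `populations`
#'   (tibble per random set), `frac_random_larger_sd`,
#'   `frac_random_larger_iqr`, `missing` (ids not found).
#' @export
complex_vs_random <- function(members, halflife_table, n_populations = 10,
                              seed = 1) {
  found <- intersect(members, halflife_table$protein_id)
  missing <- setdiff(members, halflife_table$protein_id)
  if (length(found) < 3) {
    stop("fewer than 3 complex members found in the half-life table; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hl <- halflife_table$mean[match(found, halflife_table$protein_id)]
  cx <- tibble::tibble(n = length(found), sd = stats::sd(hl),
                       iqr = stats::IQR(hl))
  pops <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_populations), function(i) {
      draw <- sample(halflife_table$mean, size = length(found),
                     replace = FALSE)
      tibble::tibble(population = i, sd = stats::sd(draw),
                     iqr = stats::IQR(draw),
                     members = list(sort(draw)))
    })
  })
  list(complex = cx,
       populations = pops,
       frac_random_larger_sd = mean(pops$sd > cx$sd),
       frac_random_larger_iqr = mean(pops$iqr > cx$iqr),
       missing = missing)
}
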