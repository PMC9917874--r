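#' Read a peptide-level quantification table
#'
#' Reads a delimited export of peptide-level SILAC quantifications into the
#' canonical tibble used throughout the package: one row per peptide
#' observation with subject, group, time point, protein accession, peptide
#' identifier, heavy/light ratio, summed (light + heavy) peak intensity and
#' run identifier.
#'
#' Rows whose ratio is missing or unparseable are dropped, not zero-filled:
#' an undetectable heavy signal at an early time point carries no ratio
#' information, and the kinetic fit uses only observed ratios. The number of
#' dropped rows and their row indices are attached as the `"drop_report"`
#' attribute.
#'
#' @param path Path to a TSV (canonical) or CSV file with a header row.
#'   Files ending in `.csv` are read comma-separated, anything else
#'   tab-separated.
#' @param col_map Optional named character vector remapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(ratio_hl = "Ratio H/L", protein_id = "Accession")`. Canonical names:
#'   `subject_id`, `group`, `time_h`, `protein_id`, `peptide_id`,
#'   `ratio_hl`, `intensity`, `run_id`.
#' @param ratio_orientation `"HL"` (default) if the ratio column is
#'   heavy-over-light, `"LH"` if the export reports light-over-heavy, in
#'   which case ratios are inverted on load.
#' @param times_h Design time points in hours; rows whose `time_h` is not
#'   one of these raise an error. `NULL` (default) skips the check.
#' @param strict_unique_peptides If `TRUE`, peptide identifiers mapped to
#'   more than one protein accession are dropped (and counted in the drop
#'   report); the default assumes unique-peptide filtering was done upstream.
#'
#' @return A tibble of validated peptide measurements, in file order, with a
#'   `"drop_report"` attribute (tibble with `reason` and `n`).
#' @export
read_peptide_table <- function(path, col_map = NULL,
                               ratio_orientation = c("HL", "LH"),
                               times_h = NULL,
                               strict_unique_peptides = FALSE) {
  ratio_orientation <- match.arg(ratio_orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)

  canonical <- c("subject_id", "group", "time_h", "protein_id", "peptide_id",
                 "ratio_hl", "intensity", "run_id")
  file_names <- canonical
  names(file_names) <- canonical
  if (!is.null(col_map)) file_names[names(col_map)] <- unname(col_map)

  missing_cols <- canonical[!file_names %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("required column(s) missing from ", path, ": ",
         paste0(missing_cols, " (expected file column '",
                file_names[missing_cols], "')", collapse = ", "),
         call. = FALSE)
  }

  x <- tibble::tibble(
    subject_id = raw[[file_names[["subject_id"]]]],
    group      = raw[[file_names[["group"]]]],
    time_h     = suppressWarnings(as.numeric(raw[[file_names[["time_h"]]]])),
    protein_id = raw[[file_names[["protein_id"]]]],
    peptide_id = raw[[file_names[["peptide_id"]]]],
    ratio_hl   = suppressWarnings(as.numeric(raw[[file_names[["ratio_hl"]]]])),
    intensity  = suppressWarnings(as.numeric(raw[[file_names[["intensity"]]]])),
    run_id     = raw[[file_names[["run_id"]]]]
  )

  if (anyNA(x$time_h)) {
    stop("unparseable time_h value at row(s) ",
         paste(utils::head(which(is.na(x$time_h)), 5), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(times_h) && !all(x$time_h %in% times_h)) {
    bad <- which(!x$time_h %in% times_h)[1]
    stop("time_h value ", x$time_h[bad], " at row ", bad,
         " is not a design time point (", paste(times_h, collapse = ", "), ")",
         call. = FALSE)
  }

  drops <- list()
  na_ratio <- is.na(x$ratio_hl)
  if (any(na_ratio)) {
    drops$missing_ratio <- sum(na_ratio)
    x <- x[!na_ratio, , drop = FALSE]
  }

  neg_ratio <- which(x$ratio_hl < 0)
  if (length(neg_ratio) > 0) {
    stop("negative ratio_hl at row ", neg_ratio[1], call. = FALSE)
  }
  neg_int <- which(!is.na(x$intensity) & x$intensity < 0)
  if (length(neg_int) > 0) {
    stop("negative intensity at row ", neg_int[1], call. = FALSE)
  }

  if (ratio_orientation == "LH") {
    zero <- x$ratio_hl == 0
    if (any(zero)) {
      drops$zero_lh_ratio <- sum(zero)
      x <- x[!zero, , drop = FALSE]
    }
    x$ratio_hl <- 1 / x$ratio_hl
  }

  if (strict_unique_peptides) {
    multi <- x |>
      dplyr::distinct(.data$peptide_id, .data$protein_id) |>
      dplyr::count(.data$peptide_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(multi) > 0) {
      shared <- x$peptide_id %in% multi$peptide_id
      drops$shared_peptide <- sum(shared)
      x <- x[!shared, , drop = FALSE]
    }
  }

  x <- dplyr::distinct(x, .data$subject_id, .data$time_h, .data$run_id,
                       .data$peptide_id, .keep_all = TRUE)

  report <- tibble::tibble(
    reason = names(drops),
    n = as.integer(unlist(drops, use.names = FALSE))
  )
  if (nrow(report) == 0) report <- tibble::tibble(reason = character(), n = integer())
  attr(x, "drop_report") <- report
  x
}

#' Write a peptide table to disk
#'
#' Writes the canonical tab-separated peptide table (or CSV when the path
#' ends in `.csv`). Numeric columns are serialized at full precision so a
#' read/write/read cycle round-trips the values exactly.
#'
#' @param x Peptide measurement tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_peptide_table <- function(x, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(x, path)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(x)
}

#' Aggregate peptide ratios to protein-level H/L ratios
#'
#' Collapses peptide observations to one row per (protein, subject, time
#' point). The protein-level ratio `r` is the median of the contributing
#' peptide ratios (midpoint of the two central values for even counts) —
#' robust against a single aberrant peptide. The spread of the same peptide
#' set is summarised as the sample standard deviation (`n - 1` denominator;
#' 0 when a single peptide is observed) and as a coefficient of variation in
#' percent, `100 * sd / mean`.
#'
#' Proteins observed through a single peptide at a time point are retained
#' with `sd_peptides = 0`, `cv_peptides = 0` and `single_peptide = TRUE`:
#' the downstream CV filter targets disagreement between peptides, which a
#' singleton cannot exhibit. When the peptide mean is zero the CV is
#' undefined and `cv_defined` is `FALSE`.
#'
#' @param measurements Peptide measurement tibble (see
#'   [read_peptide_table()]).
#' @return A tibble with one row per (protein_id, subject_id, time_h):
#'   `group`, `r`, `n_peptides`, `sd_peptides`, `cv_peptides`,
#'   `single_peptide`, `cv_defined`.
#' @export
aggregate_protein_ratios <- function(measurements) {
  if (is.null(measurements) || nrow(measurements) == 0) {
    stop("no peptide measurements to aggregate", call. = FALSE)
  }
  measurements |>
    dplyr::group_by(.data$protein_id, .data$subject_id, .data$time_h) |>
    dplyr::summarise(
      group = dplyr::first(.data$group),
      r = stats::median(.data$ratio_hl),
      n_peptides = dplyr::n(),
      sd_peptides = ifelse(dplyr::n() == 1, 0, stats::sd(.data$ratio_hl)),
      mean_peptides = mean(.data$ratio_hl),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cv_defined = .data$mean_peptides > 0,
      cv_peptides = dplyr::if_else(.data$cv_defined,
                                   100 * .data$sd_peptides / .data$mean_peptides,
                                   NA_real_),
      single_peptide = .data$n_peptides == 1
    ) |>
    dplyr::select(-"mean_peptides")
}

#' Filter protein measurements by peptide coefficient of variation
#'
#' Removes protein-level measurements whose across-peptide CV exceeds
#' `max_cv_pct` (strictly greater than; a measurement at exactly the
#' threshold is retained). Single-peptide measurements carry CV 0 and pass;
#' measurements with an undefined CV (peptide mean 0) are retained and left
#' flagged. Per-subject, per-time exclusion counts are attached as the
#' `"exclusion_report"` attribute.
#'
#' @param protein_ratios Output of [aggregate_protein_ratios()].
#' @param max_cv_pct CV threshold in percent (default 50).
#' @return The retained rows, with an `"exclusion_report"` attribute.
#' @export
filter_measurement_cv <- function(protein_ratios, max_cv_pct = 50) {
  excluded <- !is.na(protein_ratios$cv_peptides) &
    protein_ratios$cv_peptides > max_cv_pct
  report <- protein_ratios[excluded, , drop = FALSE] |>
    dplyr::count(.data$subject_id, .data$time_h, name = "n_excluded")
  out <- protein_ratios[!excluded, , drop = FALSE]
  attr(out, "exclusion_report") <- report
  out
}
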