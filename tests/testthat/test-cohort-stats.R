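subj_values <- function(protein, values, group, prefix) {
  tibble::tibble(protein_id = protein,
                 subject_id = paste0(prefix, seq_along(values)),
                 group = group, value = values)
}

two_group <- function(protein, a, b) {
  dplyr::bind_rows(
    subj_values(protein, a, "control_diabetic", "D"),
    subj_values(protein, b, "nephropathic", "N"))
}

test_that("per-protein summaries require at least two subjects", {
  x <- dplyr::bind_rows(
    subj_values("A", c(20, 30), "control_diabetic", "D"),
    subj_values("B", 25, "control_diabetic", "D"),
    subj_values("C", rep(40, 10), "control_diabetic", "D"))
  s <- summarize_protein(x, value)
  expect_setequal(s$protein_id, c("A", "C"))
  expect_equal(s$mean[s$protein_id == "A"], 25)
  expect_equal(s$sd[s$protein_id == "C"], 0)
})

test_that("group comparison reproduces a hand-computed pooled t-test", {
  x <- two_group("A", c(10, 11, 12), c(20, 21, 22))
  cmp <- compare_groups(x, value, variable = "half_life")
  # explicit pooled-variance t statistic and CDF evaluation
  a <- c(10, 11, 12); b <- c(20, 21, 22)
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * stats::pt(-abs(tstat), df = 4)
  expect_equal(cmp$p_value, p_oracle)
  expect_equal(cmp$mean_a, 11)
  expect_equal(cmp$mean_b, 21)
  expect_true(is.na(cmp$fold_change))
})

test_that("identical groups give p = 1; degenerate zero variance is flagged", {
  same <- two_group("A", c(5, 5, 5), c(5, 5, 5))
  cmp <- compare_groups(same, value, variable = "abundance")
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$fold_change, 1)

  degen <- two_group("B", c(5, 5, 5), c(7, 7, 7))
  cmp2 <- compare_groups(degen, value, variable = "half_life")
  expect_true(cmp2$degenerate)
  expect_equal(cmp2$p_value, .Machine$double.xmin)
})

test_that("proteins with fewer than two subjects per group are skipped with a reason", {
  x <- dplyr::bind_rows(
    subj_values("A", 10, "control_diabetic", "D"),
    subj_values("A", c(20, 21, 22, 23, 24), "nephropathic", "N"))
  cmp <- compare_groups(x, value, variable = "half_life")
  expect_equal(nrow(cmp), 0)
  sk <- attr(cmp, "skipped")
  expect_equal(sk$protein_id, "A")
  expect_equal(sk$reason, "insufficient subjects")
})

test_that("fold change is the signed ratio of group means", {
  up <- compare_groups(two_group("A", c(1, 1.2), c(2, 2.2)), value,
                       variable = "abundance")
  expect_equal(up$fold_change, mean(c(2, 2.2)) / mean(c(1, 1.2)))
  down <- compare_groups(two_group("A", c(2, 2.2), c(1, 1.2)), value,
                         variable = "abundance")
  expect_equal(down$fold_change, -mean(c(2, 2.2)) / mean(c(1, 1.2)))
  expect_true(abs(down$fold_change) >= 1)
})

test_that("BH-adjusted p-values are monotone in the raw p-values", {
  set.seed(4)
  x <- purrr::map_dfr(1:30, function(i) {
    two_group(sprintf("P%02d", i), stats::rnorm(5, 50, 5),
              stats::rnorm(5, 50 + (i %% 3) * 3, 5))
  })
  cmp <- compare_groups(x, value, variable = "half_life")
  o <- order(cmp$p_value)
  expect_true(all(diff(cmp$fdr_bh[o]) >= -1e-12))
  expect_true(all(cmp$fdr_bh >= cmp$p_value - 1e-12))
})

test_that("half-life binning uses left-closed intervals over the nine ranges", {
  x <- tibble::tibble(protein_id = c("A", "B", "C", "D", "E"),
                      mean = c(15, 90, 59.9, 20, -3))
  b <- bin_by_halflife(x, mean)
  expect_equal(as.character(b$bin[b$protein_id == "A"]), "<20")
  expect_equal(as.character(b$bin[b$protein_id == "B"]), ">=90")
  expect_equal(as.character(b$bin[b$protein_id == "C"]), "[50,60)")
  expect_equal(as.character(b$bin[b$protein_id == "D"]), "[20,30)")
  expect_false("E" %in% b$protein_id)  # non-positive excluded
  expect_equal(attr(b, "excluded")$protein_id, "E")
  counts <- attr(b, "bin_counts")
  expect_equal(sum(counts$n), 4)
  expect_equal(nrow(counts), 9)
})

test_that("abundance binning covers the eight log2 ranges and partitions input", {
  x <- tibble::tibble(protein_id = sprintf("P%02d", 1:6),
                      mean = c(9.5, 7.25, 4.2, 5.0, 8.99, 6.5))
  b <- bin_by_abundance(x, mean)
  expect_equal(as.character(b$bin[b$protein_id == "P01"]), ">=9")
  expect_equal(as.character(b$bin[b$protein_id == "P02"]), "[7,7.5)")
  expect_equal(as.character(b$bin[b$protein_id == "P03"]), "<5")
  expect_equal(as.character(b$bin[b$protein_id == "P04"]), "[5,6)")
  counts <- attr(b, "bin_counts")
  expect_equal(sum(counts$n), 6)
  expect_equal(nrow(counts), 8)
  # permutation invariance of counts
  b2 <- bin_by_abundance(x[sample(6), ], mean)
  expect_equal(attr(b2, "bin_counts")$n, counts$n)
})

test_that("quadrant classification is deterministic with ties going high", {
  x <- tibble::tibble(protein_id = c("A", "B", "C", "D", "E"),
                      abund = c(10, 10, 1, 1, NA),
                      k = c(0.01, 0.1, 0.1, 0.01, 0.05))
  q <- quadrant_classify(x, abund, k, k_threshold = 0.05,
                         abundance_threshold = 5)
  expect_equal(as.character(q$quadrant),
               c("low-k/high-A", "high-k/high-A", "high-k/low-A",
                 "low-k/low-A", NA))
  # both exactly at thresholds -> high side
  tie <- quadrant_classify(tibble::tibble(protein_id = "T", abund = 5, k = 0.05),
                           abund, k, 0.05, 5)
  expect_equal(as.character(tie$quadrant), "high-k/high-A")
  # classified quadrants partition the classified proteins
  expect_equal(sum(table(q$quadrant)), 4)
})

test_that("complex dispersion is compared against seeded random populations", {
  set.seed(1)
  tbl <- tibble::tibble(protein_id = sprintf("P%03d", 1:200),
                        mean = stats::rlnorm(200, log(50), 0.6))
  members <- c("P001", "P002", "P003", "P004")
  tbl$mean[1:4] <- 42  # perfectly coherent complex
  rep1 <- complex_vs_random(members, tbl, seed = 99)
  expect_equal(rep1$complex$sd, 0)
  expect_equal(rep1$frac_random_larger_sd, 1)

  # same seed reproduces the same populations
  rep2 <- complex_vs_random(members, tbl, seed = 99)
  expect_identical(rep1$populations, rep2$populations)
  rep3 <- complex_vs_random(members, tbl, seed = 100)
  expect_false(identical(rep1$populations$sd, rep3$populations$sd))

  expect_error(complex_vs_random(c("P001", "P002", "NOPE"), tbl),
               "NOPE")
})

test_that("a random 'complex' is not called coherent: null fraction is uniform-ish", {
  set.seed(2)
  tbl <- tibble::tibble(protein_id = sprintf("P%03d", 1:300),
                        mean = stats::rlnorm(300, log(50), 0.6))
  fracs <- vapply(1:40, function(s) {
    members <- sample(tbl$protein_id, 8)
    complex_vs_random(members, tbl, seed = s)$frac_random_larger_sd
  }, numeric(1))
  # under the null the fraction should wander over [0, 1], centred near 1/2
  expect_gt(mean(fracs), 0.25)
  expect_lt(mean(fracs), 0.75)
  expect_gt(length(unique(fracs)), 3)
})
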