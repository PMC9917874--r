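test_that("predict_sd evaluates the two-parameter noise law", {
  m <- noise_model(0.02, 0.1)
  expect_identical(predict_sd(m, 0), 0.02)
  expect_equal(predict_sd(m, 1), sqrt(0.0004 + 0.01))
  # large-r asymptote: SD/r -> beta
  expect_equal(predict_sd(m, 1e6) / 1e6, 0.1, tolerance = 1e-9)
  expect_error(predict_sd(m, -0.1), "non-negative")
})

test_that("predict_sd is monotone non-decreasing in r", {
  m <- noise_model(0.02, 0.1)
  r <- seq(0, 5, length.out = 200)
  expect_true(all(diff(predict_sd(m, r)) >= 0))
  # and the implied CV is non-increasing for r > 0
  rp <- r[r > 0]
  expect_true(all(diff(predict_sd(m, rp) / rp) <= 0))
})

test_that("noise_model rejects invalid parameters", {
  expect_error(noise_model(-0.1, 0.1), "non-negative")
  expect_error(noise_model(0, 0), "both")
})

test_that("bins tile the range and merge rightward when under-filled", {
  # 30 measurements placed to give exactly 10 per 0.05-wide bin
  r <- c(seq(0.00, 0.049, length.out = 10),
         seq(0.05, 0.099, length.out = 10),
         seq(0.10, 0.149, length.out = 10))
  pr <- tibble::tibble(protein_id = sprintf("P%02d", seq_along(r)),
                       subject_id = "S1", time_h = 4,
                       group = "g", r = r, n_peptides = 3L,
                       sd_peptides = 0.01, cv_peptides = 10,
                       single_peptide = FALSE, cv_defined = TRUE)
  b <- bin_ratios(pr, bin_size = 0.05, min_count = 10)
  expect_equal(nrow(b), 3)
  expect_equal(b$n, c(10L, 10L, 10L))
  expect_false(any(b$underfilled))
  # bins tile without overlap
  expect_equal(b$r_lo[-1], b$r_hi[-nrow(b)])

  # 12 in the first window, 3 in the second: the trailing bin stays
  # under-filled and flagged
  r2 <- c(seq(0.00, 0.049, length.out = 12), c(0.06, 0.07, 0.08))
  pr2 <- pr[seq_along(r2), ]
  pr2$r <- r2
  b2 <- bin_ratios(pr2, bin_size = 0.05, min_count = 10)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$n, c(12L, 3L))
  expect_true(b2$underfilled[2])
})

test_that("bin medians are medians of member SDs", {
  pr <- tibble::tibble(protein_id = c("A", "B", "C"), subject_id = "S1",
                       time_h = 4, group = "g", r = c(0.01, 0.02, 0.03),
                       n_peptides = 3L, sd_peptides = c(0.01, 0.02, 0.03),
                       cv_peptides = c(10, 20, 30), single_peptide = FALSE,
                       cv_defined = TRUE)
  b <- bin_ratios(pr, bin_size = 0.05, min_count = 3)
  expect_equal(b$median_sd, 0.02)
  expect_equal(b$median_cv, 20)
})

test_that("fitting noiseless bins recovers the generating constants", {
  r_mid <- seq(0.025, 0.975, by = 0.05)
  bins <- tibble::tibble(r_lo = r_mid - 0.025, r_hi = r_mid + 0.025,
                         r_mid = r_mid, n = 50L,
                         median_sd = sqrt(0.02^2 + 0.1^2 * r_mid^2),
                         median_cv = 100 * sqrt(0.02^2 + 0.1^2 * r_mid^2) / r_mid,
                         underfilled = FALSE)
  m <- fit_noise_model(bins)
  expect_equal(m$alpha, 0.02, tolerance = 1e-6)
  expect_equal(m$beta, 0.1, tolerance = 1e-6)
  expect_equal(m$source, "fitted")
})

test_that("flat SD near r = 0 collapses to the additive term", {
  bins <- tibble::tibble(r_lo = seq(0, 0.004, by = 0.001),
                         r_hi = seq(0.001, 0.005, by = 0.001),
                         n = 20L, median_sd = 0.03, median_cv = 5,
                         underfilled = FALSE) |>
    dplyr::mutate(r_mid = (r_lo + r_hi) / 2)
  m <- fit_noise_model(bins)
  expect_equal(m$alpha, 0.03, tolerance = 1e-4)
  expect_lt(m$beta * max(bins$r_mid), 0.001)
})

test_that("fewer than 3 bins is an error", {
  bins <- tibble::tibble(r_lo = c(0, 0.05), r_hi = c(0.05, 0.1),
                         r_mid = c(0.025, 0.075), n = 10L,
                         median_sd = 0.02, median_cv = 10,
                         underfilled = FALSE)
  expect_error(fit_noise_model(bins), "3 bins")
})

test_that("fitted minimiser matches a brute-force grid search", {
  # random bin sets; brute-force scan over alpha in [0, 0.1], beta in
  # [0, 0.5], refined to a 1e-4 step around the coarse optimum
  grid_scan <- function(bins, alphas, betas) {
    best <- c(NA, NA); best_v <- Inf
    for (a in alphas) {
      pred <- sqrt(outer(betas^2, bins$r_mid^2) + a^2)  # nb x nbins
      sse <- rowSums(sweep(pred, 2, bins$median_sd)^2)
      i <- which.min(sse)
      if (sse[i] < best_v) { best_v <- sse[i]; best <- c(a, betas[i]) }
    }
    best
  }
  grid_min <- function(bins) {
    coarse <- grid_scan(bins, seq(0, 0.1, by = 1e-3), seq(0, 0.5, by = 1e-3))
    grid_scan(bins,
              seq(max(0, coarse[1] - 2e-3), min(0.1, coarse[1] + 2e-3), by = 1e-4),
              seq(max(0, coarse[2] - 2e-3), min(0.5, coarse[2] + 2e-3), by = 1e-4))
  }
  set.seed(5)
  for (i in 1:5) {
    # keep the optimum strictly inside the scanned box
    a_true <- stats::runif(1, 0.005, 0.06)
    b_true <- stats::runif(1, 0.02, 0.4)
    r_mid <- sort(stats::runif(8, 0.05, 1.2))
    bins <- tibble::tibble(r_lo = r_mid - 0.02, r_hi = r_mid + 0.02,
                           r_mid = r_mid, n = 30L,
                           median_sd = sqrt(a_true^2 + b_true^2 * r_mid^2) *
                             exp(stats::rnorm(8, 0, 0.05)),
                           median_cv = 10, underfilled = FALSE)
    m <- fit_noise_model(bins)
    g <- grid_min(bins)
    expect_lt(abs(m$alpha - g[1]), 1.5e-4)
    expect_lt(abs(m$beta - g[2]), 1.5e-4)
    # and the analytic fit is never worse than the brute-force scan
    obj <- function(p) sum((bins$median_sd -
                              sqrt(p[1]^2 + p[2]^2 * bins$r_mid^2))^2)
    expect_lte(obj(c(m$alpha, m$beta)), obj(g) + 1e-12)
  }
})

test_that("fitting is scale-consistent: scaling r and SD scales alpha, not beta", {
  set.seed(9)
  r_mid <- seq(0.05, 1, by = 0.05)
  sd0 <- sqrt(0.02^2 + 0.1^2 * r_mid^2) * exp(stats::rnorm(length(r_mid), 0, 0.03))
  mk <- function(r, s) tibble::tibble(r_lo = r - 0.025, r_hi = r + 0.025,
                                      r_mid = r, n = 40L, median_sd = s,
                                      median_cv = 10, underfilled = FALSE)
  m1 <- fit_noise_model(mk(r_mid, sd0))
  c_scale <- 3
  m2 <- fit_noise_model(mk(r_mid * c_scale, sd0 * c_scale))
  expect_equal(m2$alpha, c_scale * m1$alpha, tolerance = 1e-3)
  expect_equal(m2$beta, m1$beta, tolerance = 1e-3)
})

test_that("parameters are recovered within 10% from sampled bins", {
  # bins carrying sampling noise: each bin median computed from >= 200
  # simulated protein SDs (10 replicates each)
  set.seed(21)
  r_mid <- seq(0.075, 1.175, by = 0.05)
  med_sd <- vapply(r_mid, function(r) {
    sds <- vapply(seq_len(200), function(i) {
      stats::sd(stats::rnorm(10, r, sqrt(0.02^2 + 0.1^2 * r^2)))
    }, numeric(1))
    stats::median(sds)
  }, numeric(1))
  bins <- tibble::tibble(r_lo = r_mid - 0.025, r_hi = r_mid + 0.025,
                         r_mid = r_mid, n = 200L, median_sd = med_sd,
                         median_cv = 100 * med_sd / r_mid,
                         underfilled = FALSE)
  m <- fit_noise_model(bins)
  expect_lt(abs(m$alpha - 0.02) / 0.02, 0.10)
  expect_lt(abs(m$beta - 0.1) / 0.1, 0.10)
})

test_that("trend diagnostic rejects both constant models only when warranted", {
  r_mid <- seq(0.075, 1.075, by = 0.1)
  mk <- function(sd, cv) tibble::tibble(r_lo = r_mid - 0.05,
                                        r_hi = r_mid + 0.05, r_mid = r_mid,
                                        n = 20L, median_sd = sd,
                                        median_cv = cv, underfilled = FALSE)
  model_bins <- mk(sqrt(0.02^2 + 0.1^2 * r_mid^2),
                   100 * sqrt(0.02^2 + 0.1^2 * r_mid^2) / r_mid)
  d <- constant_model_diagnostic(model_bins)
  expect_true(d$reject_constant_sd)
  expect_true(d$reject_constant_cv)
  expect_gt(d$sd_trend, 0)
  expect_lt(d$cv_trend, 0)

  flat_sd <- mk(rep(0.02, length(r_mid)), 100 * 0.02 / r_mid)
  d2 <- constant_model_diagnostic(flat_sd)
  expect_false(d2$reject_constant_sd)

  prop <- mk(0.1 * r_mid, rep(10, length(r_mid)))
  d3 <- constant_model_diagnostic(prop)
  expect_false(d3$reject_constant_cv)
  expect_true(d3$reject_constant_sd)
})

test_that("noise model round-trips through its text serialization", {
  m <- noise_model(0.0213456789, 0.0987654321, source = "fitted")
  path <- tempfile(fileext = ".txt")
  write_noise_model(m, path)
  m2 <- read_noise_model(path)
  expect_identical(m2$alpha, m$alpha)
  expect_identical(m2$beta, m$beta)
  expect_identical(m2$source, "fitted")
})

test_that("tidy and glance summarise a fitted model", {
  m <- noise_model(0.02, 0.1)
  td <- tidy(m)
  expect_equal(td$term, c("alpha", "beta"))
  expect_equal(td$estimate, c(0.02, 0.1))
  gl <- glance(m)
  expect_equal(gl$source, "fixed")
  expect_equal(nrow(gl), 1)
})
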