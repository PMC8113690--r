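# A compact per-participant ROI-coherence table covering every 0.5 Hz bin,
# for null-distribution bookkeeping tests.
make_roi_table <- function(n_participants = 47, seed = 1) {
  withr::with_seed(seed, {
    tidyr::expand_grid(participant_id = sprintf("P%03d", 1:n_participants),
                       freq_hz = seq(0.5, 49.5, by = 0.5)) |>
      dplyr::mutate(value = stats::runif(dplyr::n(), 0, 0.1))
  })
}

test_that("chance null pools resamples x frequencies with exact bookkeeping", {
  roi <- make_roi_table()
  null <- build_chance_null(roi, group_size = 16, seed = 3)
  expect_equal(length(null$pooled_values), 50000)
  expect_equal(length(null$chance_freqs), 50)
  expect_equal(null$chance_freqs, seq(0.5, 49.5, by = 1))
  expect_true(all(null$pooled_values >= 0))
  # determinism
  null2 <- build_chance_null(roi, group_size = 16, seed = 3)
  expect_identical(null$pooled_values, null2$pooled_values)
  # single resample, single frequency
  n1 <- build_chance_null(roi, group_size = 5, n_resamples = 1,
                          chance_freqs = 0.5, seed = 1)
  expect_length(n1$pooled_values, 1)
  expect_error(build_chance_null(dplyr::filter(roi, freq_hz > 1),
                                 group_size = 5), "missing")
  expect_error(build_chance_null(roi, group_size = 100), "exceeds")
})

test_that("empirical p is one-sided, floored, and monotone", {
  roi <- make_roi_table(n_participants = 10)
  null <- build_chance_null(roi, group_size = 4, n_resamples = 100, seed = 2)
  n_pool <- length(null$pooled_values)
  top <- empirical_p(max(null$pooled_values) + 1, null)
  expect_equal(top$p_value, 1 / n_pool)      # floored, never 0
  expect_equal(top$n_exceed, 0)
  bottom <- empirical_p(-1, null)
  expect_equal(bottom$p_value, 1)
  med <- empirical_p(stats::median(null$pooled_values), null)
  expect_equal(med$p_value, 0.5, tolerance = 2 / sqrt(n_pool))
  # monotone non-increasing in the observation
  obs <- seq(0, 0.12, length.out = 30)
  ps <- empirical_p(obs, null)$p_value
  expect_true(all(diff(ps) <= 0))
})

test_that("FDR correction reproduces a hand-executed BH step-up", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.2)
  res <- fdr_correct(p, alpha = 0.05)
  expect_identical(res$significant, oracle_bh_reject(p, 0.05))
  expect_identical(res$significant, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # all p below alpha are all rejected
  expect_true(all(fdr_correct(rep(0.005, 7), alpha = 0.01)$significant))
  # single p: reject iff p <= alpha
  expect_true(fdr_correct(0.01, alpha = 0.01)$significant)
  expect_false(fdr_correct(0.011, alpha = 0.01)$significant)
  expect_error(fdr_correct(c(0.2, 1.7)), "\\[0, 1\\]")
})

test_that("bootstrap comparison obeys its counting rule", {
  a <- c(10, 11, 12, 13); b <- c(1, 2, 3)
  res <- bootstrap_compare(a, b, n = 5000, seed = 1)
  expect_equal(res$p_value, 1 / 5001)        # no overlap: N = 0
  expect_equal(res$n_contra, 0)
  # n = 1 with a guaranteed contradiction of the stated direction
  res1 <- bootstrap_compare(c(1, 1, 1), c(5, 5, 5.00001), n = 1, seed = 1,
                            alternative = "greater")
  expect_equal(res1$p_value, 1)
  # identical groups: p close to 1/2 on average
  ps <- withr::with_seed(6, vapply(1:50, function(i) {
    g <- stats::rnorm(10)
    bootstrap_compare(g, g, n = 400, seed = i)$p_value
  }, numeric(1)))
  expect_equal(mean(ps), 0.5, tolerance = 0.1)
  # swapping groups with the direction flipped gives the same p up to
  # Monte-Carlo error
  withr::with_seed(7, { x <- stats::rnorm(12, 1); y <- stats::rnorm(12) })
  p_ab <- bootstrap_compare(x, y, n = 4000, seed = 5,
                            alternative = "greater")$p_value
  p_ba <- bootstrap_compare(y, x, n = 4000, seed = 6,
                            alternative = "less")$p_value
  expect_equal(p_ab, p_ba, tolerance = 0.02)
  expect_true(p_ab >= 1 / 4001 && p_ab <= 1)
  expect_error(bootstrap_compare(rep(2, 5), rep(2, 5)), "degenerate")
  expect_error(bootstrap_compare(1:2, 1:5), "at least 3")
})

test_that("Rayleigh p-values follow exp(-z), meeting the z > 3 criterion", {
  expect_lte(rayleigh_p(3), 0.05)
  expect_equal(rayleigh_p(3), exp(-3))
  expect_equal(rayleigh_p(0), 1)
  expect_equal(rayleigh_p(10), exp(-10))
  # finite-sample refinement stays close for moderate T and valid
  expect_equal(rayleigh_p(3, n_segments = 450), exp(-3), tolerance = 0.01)
  expect_error(rayleigh_p(-1), "non-negative")
})

test_that("score correlations handle exact fits, independence, and outliers", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  res <- correlate_scores(d, "x", "y", outlier_rule = "none")
  expect_equal(res$r, 1)
  # independent variables: |r| small at n = 1000
  d2 <- withr::with_seed(31, tibble::tibble(x = stats::rnorm(1000),
                                            y = stats::rnorm(1000)))
  expect_lt(abs(correlate_scores(d2, "x", "y")$r), 0.08)
  # gross outlier removed; r then matches the direct formula on the rest
  d3 <- tibble::tibble(id = letters[1:7],
                       x = c(1, 2, 3, 4, 5, 6, 4),
                       y = c(1.1, 1.9, 3.2, 3.9, 5.1, 6.0, 40))
  res3 <- correlate_scores(d3, "x", "y")
  expect_equal(res3$removed_id, "g")
  keep <- d3$id != "g"
  expect_equal(res3$r, stats::cor(d3$x[keep], d3$y[keep]))
  expect_equal(res3$n, 6)
  expect_error(correlate_scores(tibble::tibble(x = 1:3, y = 3:1), "x", "y"),
               "at least 4")
  expect_error(correlate_scores(tibble::tibble(x = rep(1, 8), y = 1:8),
                                "x", "y", outlier_rule = "none"),
               "zero variance")
})

test_that("correlation table is corrected as one family and finds real links", {
  # one strong link among noise survives at q = 0.05
  d <- withr::with_seed(32, {
    n <- 40
    x1 <- stats::rnorm(n)
    tibble::tibble(coh_41 = x1, coh_41pm2 = stats::rnorm(n),
                   coh_2 = stats::rnorm(n), coh_4 = stats::rnorm(n),
                   coh_delta = stats::rnorm(n), coh_theta = stats::rnorm(n),
                   crsr_baseline = 10 + 5 * x1 + stats::rnorm(n, 0, 0.5),
                   gose = stats::rnorm(n))
  })
  tab <- fdr_family_correlations(d, q = 0.05, outlier_rule = "none")
  expect_equal(nrow(tab), 12)
  expect_true(tab$significant[tab$feature == "coh_41" &
                                tab$score == "crsr_baseline"])
  expect_equal(tab$p_adj, stats::p.adjust(tab$p_value, "BH"))
  expect_error(fdr_family_correlations(d[, 1:3]), "missing columns")
})

test_that("a built-in 41 Hz link to CRS-R is detected in most cohorts", {
  # power check at the generated study's conditions: target r = 0.6, n = 30
  hits <- vapply(1:40, function(s) {
    rng <- c(0.05, 0.7)
    tg <- lapply(default_coherence_targets(), function(v) {
      out <- as.list(v); out$coh_41 <- rng; out
    })
    sn <- score_noise_sd_for_rho(0.6, diff(rng) / sqrt(12), slope = 25)
    spec <- cohort_spec(n_per_group = c(HC = 1, DOC_P = 15, DOC_N = 15),
                        coherence_targets = tg, score_noise_sd = sn,
                        n_segments = 200, seed = s)
    coh <- simulate_cohort(spec, mode = "features")
    pat <- dplyr::filter(coh$features, group != "HC")
    tab <- fdr_family_correlations(pat, q = 0.05)
    tab$significant[tab$feature == "coh_41" & tab$score == "crsr_baseline"]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
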