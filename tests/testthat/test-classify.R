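# Small separable two-class feature table for classifier mechanics.
make_blobs <- function(n_per_class = 12, gap = 4, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      f1 = c(stats::rnorm(n_per_class), stats::rnorm(n_per_class) + gap),
      f2 = c(stats::rnorm(n_per_class), stats::rnorm(n_per_class) + gap),
      label = factor(rep(c("neg", "pos"), each = n_per_class),
                     levels = c("neg", "pos")))
  })
}

small_grids <- list(cost_grid = 2^seq(-3, 7, by = 2),
                    gamma_grid = 2^seq(-7, 1, by = 2))

test_that("labels encode diagnosis and outcome transitions", {
  p <- tibble::tibble(
    group = c("UWS", "MCS", "MCS", "UWS"),
    baseline_category = c("UWS", "MCS+", "MCS+", "UWS"),
    followup_category = c("MCS-", "MCS+", "MCS-", "UWS"))
  expect_equal(as.character(make_labels(p, "diagnosis")),
               c("UWS", "MCS", "MCS", "UWS"))
  # advance -> positive; stasis and retrogress -> negative
  expect_equal(as.character(make_labels(p, "prognosis")),
               c("positive", "negative", "negative", "negative"))
  expect_error(make_labels(tibble::tibble(group = "HC"), "diagnosis"),
               "healthy controls")
})

test_that("stratified split follows the rounding rule and is reproducible", {
  d <- make_blobs(20)
  sp <- split_train_test(d, seed = 4)
  expect_equal(as.integer(table(sp$train$label)), c(14, 14))
  expect_equal(as.integer(table(sp$test$label)), c(6, 6))
  sp2 <- split_train_test(d, seed = 4)
  expect_identical(sp$train, sp2$train)
  # 15 + 16 at 0.7: floor(0.7 n + 0.5) gives 11 and 11
  d2 <- tibble::tibble(label = factor(rep(c("a", "b"), times = c(15, 16))))
  sp3 <- split_train_test(d2, seed = 1)
  expect_equal(as.integer(table(sp3$train$label)), c(11, 11))
  expect_equal(as.integer(table(sp3$test$label)), c(4, 5))
  expect_error(split_train_test(
    tibble::tibble(label = factor(c("a", "b", "b")))), "at least 2")
})

test_that("grid search separates blobs and is deterministic", {
  d <- make_blobs(10, gap = 6)
  m <- do.call(fit_svm_gridsearch,
               c(list(train = d, feature_cols = c("f1", "f2"), seed = 2),
                 small_grids))
  expect_s3_class(m, "rhythm_svm")
  expect_equal(m$cv_accuracy, 1)
  m2 <- do.call(fit_svm_gridsearch,
                c(list(train = d, feature_cols = c("f1", "f2"), seed = 2),
                  small_grids))
  expect_identical(c(m$cost, m$gamma), c(m2$cost, m2$gamma))
  expect_error(fit_svm_gridsearch(dplyr::mutate(d, label = factor("pos")),
                                  c("f1", "f2")), "both classes")
})

test_that("report metrics satisfy their defining identities", {
  d <- make_blobs(10, gap = 6)
  sp <- split_train_test(d, seed = 3)
  m <- do.call(fit_svm_gridsearch,
               c(list(train = sp$train, feature_cols = c("f1", "f2"),
                      seed = 3), small_grids))
  rep_ <- evaluate_classifier(m, sp$test)
  conf <- rep_$confusion
  tp <- conf["pos", "pos"]; fn <- conf["pos", "neg"]
  tn <- conf["neg", "neg"]; fp <- conf["neg", "pos"]
  expect_equal(rep_$sensitivity, tp / (tp + fn))
  expect_equal(rep_$specificity, tn / (tn + fp))
  expect_equal(rep_$accuracy, (tp + tn) / sum(conf))
  expect_true(rep_$auc >= 0 && rep_$auc <= 1)
  # perfectly separable: everything 1
  expect_equal(unname(c(rep_$sensitivity, rep_$specificity, rep_$accuracy,
                        rep_$auc)), rep(1, 4))
  # chi-square equals the direct Pearson formula on the emitted table
  d_noisy <- make_blobs(14, gap = 1.2, seed = 9)
  spn <- split_train_test(d_noisy, seed = 5)
  mn <- do.call(fit_svm_gridsearch,
                c(list(train = spn$train, feature_cols = c("f1", "f2"),
                       seed = 5), small_grids))
  rn <- evaluate_classifier(mn, spn$test)
  expect_equal(rn$chi2, oracle_chisq(unclass(rn$confusion)))
  # broom-style accessors
  expect_equal(nrow(tidy(rep_)), 6)
  expect_equal(glance(rep_)$auc, rep_$auc)
})

test_that("degenerate predictions produce the expected corner metrics", {
  # all test points predicted positive: sensitivity 1, specificity 0
  tr <- make_blobs(8, gap = 6, seed = 11)
  m <- do.call(fit_svm_gridsearch,
               c(list(train = tr, feature_cols = c("f1", "f2"), seed = 1),
                 small_grids))
  far <- tibble::tibble(f1 = rep(8, 6), f2 = rep(8, 6),
                        label = factor(rep(c("neg", "pos"), 3),
                                       levels = c("neg", "pos")))
  rep_ <- evaluate_classifier(m, far)
  expect_equal(rep_$sensitivity, 1)
  expect_equal(rep_$specificity, 0)
})

test_that("the repeated protocol is reproducible and feature-sensitive", {
  tg <- list(
    DOC_P = c(coh_41 = 0.60, coh_41pm2 = 0.45, coh_2 = 0.15, coh_4 = 0.15,
              coh_delta = 0.12, coh_theta = 0.10),
    DOC_N = c(coh_41 = 0.05, coh_41pm2 = 0.04, coh_2 = 0.15, coh_4 = 0.15,
              coh_delta = 0.12, coh_theta = 0.10),
    HC    = c(coh_41 = 0.60, coh_41pm2 = 0.45, coh_2 = 0.15, coh_4 = 0.15,
              coh_delta = 0.12, coh_theta = 0.10))
  spec <- cohort_spec(n_per_group = c(HC = 1, DOC_P = 15, DOC_N = 16),
                      coherence_targets = tg, target_jitter_sd = 0.15,
                      score_noise_sd = 0, n_segments = 200, seed = 13)
  coh <- simulate_cohort(spec, mode = "features")

  p1 <- do.call(run_protocol, c(list(coh$features, "hi", "diagnosis",
                                     n_repeats = 1, seed = 21), small_grids))
  p2 <- do.call(run_protocol, c(list(coh$features, "hi", "diagnosis",
                                     n_repeats = 1, seed = 21), small_grids))
  expect_identical(p1$per_seed, p2$per_seed)

  hi <- do.call(run_protocol, c(list(coh$features, "hi", "diagnosis",
                                     n_repeats = 8, seed = 22), small_grids))
  lo <- do.call(run_protocol, c(list(coh$features, "lo", "diagnosis",
                                     n_repeats = 8, seed = 22), small_grids))
  expect_gte(hi$summary$median_auc - lo$summary$median_auc, 0.15)
  expect_gte(hi$summary$median_auc, 0.9)

  perm <- do.call(run_protocol, c(list(coh$features, "hi", "diagnosis",
                                       n_repeats = 8, seed = 23,
                                       permute_labels = TRUE), small_grids))
  expect_true(perm$summary$median_auc >= 0.2 &&
                perm$summary$median_auc <= 0.8)
  expect_equal(glance(hi)$feature_set, "hi")
})

test_that("speech-incomplete participants are excluded from speech features", {
  spec <- cohort_spec(n_segments = 50, seed = 17)
  coh <- simulate_cohort(spec, mode = "features")
  n_incomplete <- sum(!coh$features$speech_complete)
  expect_equal(n_incomplete, 3)
  pr <- do.call(run_protocol, c(list(coh$features, "speech", "diagnosis",
                                     n_repeats = 1, seed = 1), small_grids))
  n_pat <- sum(coh$features$group != "HC")
  used <- sum(coh$features$group != "HC" & coh$features$speech_complete)
  expect_equal(pr$per_seed$n_test + pr$per_seed$n_train, used)
})
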