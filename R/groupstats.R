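# Inferential machinery: the non-integer-frequency chance null, empirical
# significance, FDR correction, bootstrap group comparisons, Rayleigh
# p-values, and clinical-score correlations.

#' Chance-level null distribution from non-integer frequencies
#'
#' For a periodic stimulus, responses are expected at integer frequencies
#' only, so the coherence at the 50 non-integer frequencies 0.5, 1.5, ...,
#' 49.5 Hz measures chance-level coherence. Because significance is assessed
#' on group-average coherence, the null is built at the group level: each
#' resample draws `group_size` participants (without replacement within a
#' draw) from the full cohort, averages their region-of-interest coherence
#' at every chance frequency, and the values are pooled across resamples and
#' frequencies. With the defaults (1,000 resamples, 50 frequencies) the pool
#' holds 50,000 values.
#'
#' @param roi_coherence Tibble with columns `participant_id`, `freq_hz`,
#'   `value` giving each participant's ROI-mean normalized coherence; must
#'   contain all chance frequencies.
#' @param group_size Number of participants averaged per resample (the size
#'   N of the group under test).
#' @param n_resamples Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param chance_freqs The chance frequencies (default `seq(0.5, 49.5)`).
#' @return A `chance_null` object: `pooled_values`, `n_resamples`,
#'   `chance_freqs`, `group_size`, `seed`.
#' @export
build_chance_null <- function(roi_coherence, group_size,
                              n_resamples = 1000, seed = 1,
                              chance_freqs = seq(0.5, 49.5, by = 1)) {
  miss <- setdiff(chance_freqs, unique(roi_coherence$freq_hz))
  if (length(miss) > 0)
    stop("chance frequency bins missing from input: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  wide <- roi_coherence |>
    dplyr::filter(.data$freq_hz %in% chance_freqs) |>
    tidyr::pivot_wider(id_cols = "participant_id", names_from = "freq_hz",
                       values_from = "value")
  m <- as.matrix(wide[, as.character(chance_freqs)])
  n_p <- nrow(m)
  if (group_size > n_p)
    stop("group_size exceeds the number of participants", call. = FALSE)
  pooled <- withr::with_seed(seed, {
    draws <- replicate(n_resamples, {
      colMeans(m[sample.int(n_p, group_size), , drop = FALSE])
    })
    as.numeric(draws)
  })
  structure(list(pooled_values = pooled, n_resamples = n_resamples,
                 chance_freqs = chance_freqs, group_size = group_size,
                 seed = seed),
            class = "chance_null")
}

#' @export
print.chance_null <- function(x, ...) {
  cat(sprintf("<chance_null: %d pooled values (%d resamples x %d frequencies), N = %d>\n",
              length(x$pooled_values), x$n_resamples, length(x$chance_freqs),
              x$group_size))
  invisible(x)
}

#' Empirical significance against the chance null
#'
#' One-sided: larger observed coherence gives smaller p. The p-value is the
#' fraction of pooled chance values at or above the observation, floored at
#' 1 over the pool size (a zero p-value would break FDR correction and
#' log-scale reporting). The raw exceedance count is reported alongside.
#'
#' @param observed Numeric vector of observed group-average coherences.
#' @param null A `chance_null`.
#' @return Tibble with `observed`, `n_exceed` (chance values >= observed),
#'   and `p_value`.
#' @export
empirical_p <- function(observed, null) {
  stopifnot(inherits(null, "chance_null"))
  pool <- null$pooled_values
  if (length(pool) == 0) stop("empty null distribution", call. = FALSE)
  ns <- vapply(observed, function(o) sum(pool >= o), numeric(1))
  tibble::tibble(observed = observed, n_exceed = ns,
                 p_value = pmax(ns / length(pool), 1 / length(pool)))
}

#' Benjamini-Hochberg FDR correction
#'
#' @param pvals P-values in \[0, 1\].
#' @param alpha Significance level applied to the adjusted p-values.
#' @return Tibble with `p_value`, `p_adj`, `significant`.
#' @export
fdr_correct <- function(pvals, alpha = 0.01) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(pvals, method = "BH")
  tibble::tibble(p_value = pvals, p_adj = adj, significant = adj <= alpha)
}

#' One-sided bootstrap comparison of two group means
#'
#' Resamples each group with replacement `n` times and counts the
#' iterations N whose resampled mean difference contradicts the tested
#' direction; the significance level is (N + 1)/(n + 1). A bias-corrected
#' and accelerated (BCa) confidence interval for the mean difference is
#' computed alongside and attached for diagnostics.
#'
#' @param group_a,group_b Numeric vectors (>= 3 values each).
#' @param n Number of bootstrap resamples (default 5000).
#' @param seed Integer seed.
#' @param alternative Direction of the one-sided test: `"greater"` (A > B,
#'   stated a priori), `"less"`, or `"auto"` (taken from the observed
#'   means; note a data-driven direction is anti-conservative under the
#'   null).
#' @param conf BCa interval coverage.
#' @return One-row tibble: `mean_a`, `mean_b`, `direction` (+1 if the
#'   tested direction is A > B), `n_boot`, `n_contra`, `p_value`,
#'   `bca_lower`, `bca_upper`.
#' @export
bootstrap_compare <- function(group_a, group_b, n = 5000, seed = 1,
                              alternative = c("greater", "less", "auto"),
                              conf = 0.95) {
  alternative <- match.arg(alternative)
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs at least 3 values", call. = FALSE)
  pooled <- c(group_a, group_b)
  if (stats::sd(pooled) == 0)
    stop("degenerate comparison: all values identical; p undefined",
         call. = FALSE)
  obs <- mean(group_a) - mean(group_b)
  direction <- switch(alternative,
                      greater = 1, less = -1,
                      auto = if (obs >= 0) 1 else -1)
  na <- length(group_a); nb <- length(group_b)
  res <- withr::with_seed(seed, {
    ma <- rowMeans(matrix(sample(group_a, na * n, replace = TRUE), nrow = n))
    mb <- rowMeans(matrix(sample(group_b, nb * n, replace = TRUE), nrow = n))
    ma - mb
  })
  n_contra <- sum(res * direction <= 0)
  p <- (n_contra + 1) / (n + 1)

  # BCa interval for the mean difference (diagnostic)
  z0 <- stats::qnorm(clip(mean(res < obs), 1 / n, 1 - 1 / n))
  jack <- c(vapply(seq_len(na), function(i)
    mean(group_a[-i]) - mean(group_b), numeric(1)),
    vapply(seq_len(nb), function(i)
      mean(group_a) - mean(group_b[-i]), numeric(1)))
  jm <- mean(jack)
  denom <- 6 * (sum((jm - jack)^2))^1.5
  acc <- if (denom == 0) 0 else sum((jm - jack)^3) / denom
  al <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  zl <- stats::qnorm(al)
  adj <- stats::pnorm(z0 + (z0 + zl) / (1 - acc * (z0 + zl)))
  ci <- stats::quantile(res, adj, names = FALSE)

  tibble::tibble(mean_a = mean(group_a), mean_b = mean(group_b),
                 direction = direction, n_boot = n, n_contra = n_contra,
                 p_value = p, bca_lower = ci[1], bca_upper = ci[2])
}

#' Rayleigh test p-value
#'
#' Large-sample significance of the Rayleigh statistic z = T R-bar^2:
#' p = exp(-z). A statistic above 3 rejects circular uniformity at
#' P < 0.05 (exp(-3) = 0.0498). When the segment count T is supplied the
#' finite-sample refinement is applied.
#'
#' @param z Rayleigh statistic (>= 0); see `rayleigh_z` in
#'   [phase_coherence()].
#' @param n_segments Optional segment count for the finite-sample
#'   correction.
#' @return P-value(s).
#' @examples
#' rayleigh_p(3) # 0.0498
#' @export
rayleigh_p <- function(z, n_segments = NULL) {
  if (any(z < 0)) stop("the Rayleigh statistic is non-negative", call. = FALSE)
  p <- exp(-z)
  if (!is.null(n_segments)) {
    n <- n_segments
    p <- p * (1 + (2 * z - z^2) / (4 * n) -
                (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  }
  clip(p, 0, 1)
}

#' Pearson correlation with single-outlier removal
#'
#' Two-tailed bivariate Pearson correlation between a coherence feature and
#' a clinical score, after removing at most one gross outlier. The default
#' rule removes the single point with the largest absolute externally
#' studentized residual of `score ~ feature` if it exceeds the threshold,
#' else removes none.
#'
#' @param data Data frame holding the variables (and optionally an `id`
#'   column used to report the removed point).
#' @param feature,score Column names (strings).
#' @param outlier_rule `"studentized"` or `"none"`.
#' @param threshold Studentized-residual threshold (default 3).
#' @return One-row tibble: `feature`, `score`, `n`, `r`, `p_value`,
#'   `removed_id` (NA when nothing was removed).
#' @export
correlate_scores <- function(data, feature, score,
                             outlier_rule = c("studentized", "none"),
                             threshold = 3) {
  outlier_rule <- match.arg(outlier_rule)
  x <- data[[feature]]; y <- data[[score]]
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  ids <- if ("id" %in% names(data)) data$id[keep] else as.character(seq_along(x))
  removed <- NA_character_
  if (outlier_rule == "studentized" && length(x) >= 5) {
    rs <- stats::rstudent(stats::lm(y ~ x))
    i <- which.max(abs(rs))
    if (abs(rs[i]) > threshold) {
      removed <- ids[i]
      x <- x[-i]; y <- y[-i]
    }
  }
  if (length(x) < 4)
    stop("need at least 4 paired observations after outlier removal",
         call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in '", if (stats::sd(x) == 0) feature else score,
         "'", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(feature = feature, score = score, n = length(x),
                 r = unname(ct$estimate), p_value = ct$p.value,
                 removed_id = removed)
}

#' Correlation table with family-wise FDR correction
#'
#' Runs [correlate_scores()] for every feature x score pair and corrects
#' the whole table as one Benjamini-Hochberg family (with the default six
#' features and two scores, 12 tests).
#'
#' @param data Data frame with feature and score columns per participant.
#' @param features,scores Column-name vectors.
#' @param q FDR level for the `significant` flag.
#' @param ... Passed to [correlate_scores()].
#' @return Tidy tibble: `feature`, `score`, `n`, `r`, `p_value`, `p_adj`,
#'   `significant`, `removed_id`.
#' @export
fdr_family_correlations <- function(data,
                                    features = c("coh_41", "coh_41pm2",
                                                 "coh_2", "coh_4",
                                                 "coh_delta", "coh_theta"),
                                    scores = c("crsr_baseline", "gose"),
                                    q = 0.05, ...) {
  miss <- setdiff(c(features, scores), names(data))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  tab <- tidyr::expand_grid(feature = features, score = scores) |>
    purrr::pmap(function(feature, score)
      correlate_scores(data, feature, score, ...)) |>
    dplyr::bind_rows()
  tab$p_adj <- stats::p.adjust(tab$p_value, method = "BH")
  tab$significant <- tab$p_adj <= q
  tab
}

#' @rdname tidy_rhythmtrack
#' @export
tidy.chance_null <- function(x, ...) {
  qs <- stats::quantile(x$pooled_values, c(0.5, 0.95, 0.99), names = FALSE)
  tibble::tibble(n_pooled = length(x$pooled_values),
                 n_resamples = x$n_resamples,
                 n_chance_freqs = length(x$chance_freqs),
                 group_size = x$group_size,
                 q50 = qs[1], q95 = qs[2], q99 = qs[3])
}
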