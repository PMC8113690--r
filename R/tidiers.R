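#' Tidy and glance methods
#'
#' Broom-style summaries of the package's result objects: `tidy()` returns
#' the per-unit detail (per-seed classifier metrics, null-distribution
#' quantiles, per-metric values of a report) and `glance()` a one-row model
#' summary.
#'
#' @param x A `classifier_report`, `protocol_result`, or `chance_null`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_rhythmtrack
NULL
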