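# End-to-end orchestration: synthesize -> preprocess -> coherence ->
# group statistics -> classification, with serialized configuration and a
# hashed output manifest.

#' ROI-mean coherence per participant
#'
#' Averages the normalized coherence over a region of interest, yielding one
#' value per participant and frequency — the unit entering the chance null
#' and the group-level significance test.
#'
#' @param spec A `coherence_spectrum` tibble (any number of participants).
#' @param roi Channel labels to average over.
#' @return Tibble `participant_id`, `condition`, `freq_hz`, `value`.
#' @export
roi_mean_coherence <- function(spec, roi = roi_centrofrontal()) {
  spec |>
    dplyr::filter(.data$channel %in% roi) |>
    dplyr::group_by(.data$participant_id, .data$condition, .data$freq_hz) |>
    dplyr::summarise(value = mean(.data$coherence_norm), .groups = "drop")
}

#' Pairwise bootstrap group comparisons of band features
#'
#' Runs [bootstrap_compare()] for every feature and group pair and corrects
#' the resulting p-values as one Benjamini-Hochberg family (each reported
#' comparison table is its own family). The tested direction is "first
#' group of the pair greater", so the default pairs encode the a priori
#' ordering HC > DOC_P > DOC_N.
#'
#' @param features Feature tibble with a grouping column and feature
#'   columns; missing feature values (e.g. participants without complete
#'   speech data) are dropped per comparison.
#' @param feature_cols Feature column names to compare.
#' @param group_col Grouping column (default `"cohort_group"`).
#' @param pairs List of 2-vectors of group labels to compare.
#' @param n Bootstrap resamples per comparison.
#' @param seed Integer seed.
#' @param alpha Level applied to the adjusted p-values.
#' @return Tidy tibble: feature, groups, means, `p_value`, `p_adj`,
#'   `significant`.
#' @export
compare_groups <- function(features,
                           feature_cols = c("coh_41", "coh_41pm2", "coh_2",
                                            "coh_4", "coh_delta",
                                            "coh_theta"),
                           group_col = "cohort_group",
                           pairs = list(c("HC", "DOC_P"), c("HC", "DOC_N"),
                                        c("DOC_P", "DOC_N")),
                           n = 5000, seed = 1, alpha = 0.01) {
  rows <- list()
  k <- 0L
  for (fe in feature_cols) {
    for (pr in pairs) {
      k <- k + 1L
      a <- features[[fe]][features[[group_col]] == pr[1]]
      b <- features[[fe]][features[[group_col]] == pr[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      res <- bootstrap_compare(a, b, n = n, seed = derive_seed(seed, k),
                               alternative = "greater")
      rows[[k]] <- dplyr::mutate(res, feature = fe, group_a = pr[1],
                                 group_b = pr[2], .before = 1)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adj <= alpha
  out
}

#' Default pipeline configuration
#'
#' @param n_per_group,n_segments,seed,n_speech_incomplete Cohort size,
#'   segments per recording, master seed, and number of speech-incomplete
#'   patients (see [cohort_spec()]).
#' @param conditions Stimulus conditions to run.
#' @param n_resamples Chance-null resamples.
#' @param classifier_sets,classifier_tasks Feature sets and tasks to run.
#' @param n_repeats Split repeats per classifier.
#' @param cost_grid,gamma_grid SVM grids.
#' @param write_edf Write each recording (and JSON sidecar) to the run
#'   directory.
#' @return Config list for [run_pipeline()].
#' @export
default_run_config <- function(n_per_group = c(HC = 16, DOC_P = 15, DOC_N = 16),
                               n_segments = 150, seed = 1,
                               n_speech_incomplete = 3,
                               conditions = c("tone", "speech"),
                               n_resamples = 1000,
                               classifier_sets = c("hi", "lo", "speech",
                                                   "combo"),
                               classifier_tasks = c("diagnosis", "prognosis"),
                               n_repeats = 10,
                               cost_grid = 2^seq(-5, 15, by = 2),
                               gamma_grid = 2^seq(-15, 3, by = 2),
                               write_edf = FALSE) {
  list(cohort = list(n_per_group = as.list(n_per_group),
                     n_segments = n_segments, seed = seed,
                     n_speech_incomplete = n_speech_incomplete),
       conditions = conditions,
       roi = roi_centrofrontal(),
       null = list(n_resamples = n_resamples),
       classifier = list(sets = classifier_sets, tasks = classifier_tasks,
                         n_repeats = n_repeats, cost_grid = cost_grid,
                         gamma_grid = gamma_grid),
       write_edf = write_edf)
}

#' Run the full analysis pipeline
#'
#' Synthesizes the cohort, preprocesses every recording (EOG regression,
#' common-average re-reference, speech sessions averaged), computes
#' coherence spectra and band features, builds the per-group chance null
#' and flags significant integer frequencies (FDR), runs the bootstrap
#' group comparisons and the clinical-score correlation table, trains the
#' configured classifiers, and writes everything (plus the verbatim config
#' and a hashed manifest) to `out_dir`. Every random stage consumes a seed
#' derived from the master seed, so a rerun with the same config reproduces
#' all numeric outputs.
#'
#' @param config Config list from [default_run_config()] or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every computed table (`participants`,
#'   `features`, `spectra_roi`, `significance`, `group_comparisons`,
#'   `correlations`, `classifier_reports`, `manifest`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  seed <- config$cohort$seed %||% 1L

  spec <- cohort_spec(
    n_per_group = unlist(config$cohort$n_per_group),
    n_segments = config$cohort$n_segments %||% 150,
    n_speech_incomplete = config$cohort$n_speech_incomplete %||% 3,
    seed = seed)
  conditions <- config$conditions %||% c("tone", "speech")
  roi <- config$roi %||% roi_centrofrontal()

  participants <- draw_participants(spec)
  duration <- spec$n_segments * 2
  stimuli <- list()
  if ("tone" %in% conditions)
    stimuli$tone <- make_modulated_tone(duration)
  if ("speech" %in% conditions)
    stimuli$speech <- make_speech_envelope(duration, rate = 100,
                                           seed = derive_seed(seed, 11))

  # Per participant: simulate, preprocess, reduce to spectra immediately so
  # the waveforms are never all held in memory at once.
  spectra <- purrr::map(seq_len(nrow(participants)), function(i) {
    p <- participants[i, ]
    conds <- conditions
    if (!p$speech_complete) conds <- setdiff(conds, "speech")
    recs <- simulate_participant_recordings(p, spec, stimuli,
                                            conditions = conds)
    out <- list()
    if (!is.null(recs$tone)) {
      rec <- preprocess_recording(recs$tone)
      if (isTRUE(config$write_edf))
        write_edf(rec, file.path(out_dir, sprintf("%s_tone.edf", p$id)))
      out$tone <- compute_coherence(rec, stimuli$tone, condition = "tone")
    }
    if (!is.null(recs$speech)) {
      s1 <- preprocess_recording(recs$speech[[1]])
      s2 <- preprocess_recording(recs$speech[[2]])
      rec <- average_sessions(s1, s2)
      if (isTRUE(config$write_edf)) {
        write_edf(s1, file.path(out_dir, sprintf("%s_speech_s1.edf", p$id)))
        write_edf(s2, file.path(out_dir, sprintf("%s_speech_s2.edf", p$id)))
      }
      out$speech <- compute_coherence(rec, stimuli$speech,
                                      condition = "speech")
    }
    dplyr::bind_rows(out)
  }) |> dplyr::bind_rows()

  spectra_roi <- roi_mean_coherence(spectra, roi)

  # band features per participant, tone and speech conditions merged
  feats <- band_features(spectra, roi)
  tone_f <- feats |> dplyr::filter(.data$condition == "tone") |>
    dplyr::select("participant_id", "coh_41", "coh_41pm2", "coh_2", "coh_4")
  features <- dplyr::left_join(participants, tone_f,
                               by = c(id = "participant_id"))
  if ("speech" %in% conditions) {
    sp_f <- feats |> dplyr::filter(.data$condition == "speech") |>
      dplyr::select("participant_id", "coh_delta", "coh_theta")
    features <- dplyr::left_join(features, sp_f,
                                 by = c(id = "participant_id"))
  }

  # per-group significance vs the chance null (tone condition)
  significance <- NULL
  if ("tone" %in% conditions) {
    tone_roi <- dplyr::filter(spectra_roi, .data$condition == "tone")
    int_freqs <- 1:49
    significance <- purrr::map(unique(participants$cohort_group), function(g) {
      ids <- participants$id[participants$cohort_group == g]
      null <- build_chance_null(tone_roi, group_size = length(ids),
                                n_resamples = config$null$n_resamples %||% 1000,
                                seed = derive_seed(seed, 21))
      obs <- tone_roi |>
        dplyr::filter(.data$participant_id %in% ids,
                      .data$freq_hz %in% int_freqs) |>
        dplyr::group_by(.data$freq_hz) |>
        dplyr::summarise(value = mean(.data$value), .groups = "drop")
      ep <- empirical_p(obs$value, null)
      fdr <- fdr_correct(ep$p_value, alpha = 0.01)
      tibble::tibble(group = g, freq_hz = obs$freq_hz,
                     observed = obs$value, n_exceed = ep$n_exceed,
                     p_value = ep$p_value, p_adj = fdr$p_adj,
                     significant = fdr$significant)
    }) |> dplyr::bind_rows()
  }

  feature_cols <- intersect(c("coh_41", "coh_41pm2", "coh_2", "coh_4",
                              "coh_delta", "coh_theta"), names(features))
  group_comparisons <- compare_groups(features, feature_cols,
                                      seed = derive_seed(seed, 31))

  patients <- dplyr::filter(features, .data$group != "HC",
                            !is.na(.data$coh_41))
  correlations <- fdr_family_correlations(
    patients, features = intersect(feature_cols, names(patients)))

  reports <- list()
  for (fs in config$classifier$sets %||% character(0)) {
    if (fs %in% c("speech", "combo") && !"speech" %in% conditions) next
    for (tk in config$classifier$tasks %||% character(0)) {
      key <- paste(fs, tk, sep = "_")
      reports[[key]] <- run_protocol(
        features, feature_set = fs, task = tk,
        n_repeats = config$classifier$n_repeats %||% 10,
        seed = derive_seed(seed, 41),
        cost_grid = config$classifier$cost_grid %||% 2^seq(-5, 15, 2),
        gamma_grid = config$classifier$gamma_grid %||% 2^seq(-15, 3, 2))
    }
  }

  wr <- function(x, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(x, f, row.names = FALSE)
    f
  }
  files <- c(
    wr(participants, "participants.csv"),
    wr(features, "features.csv"),
    wr(spectra_roi, "coherence_roi.csv"),
    if (!is.null(significance)) wr(significance, "significance.csv"),
    wr(group_comparisons, "group_comparisons.csv"),
    wr(correlations, "correlations.csv"),
    unlist(purrr::imap(reports, function(r, key)
      wr(r$per_seed, paste0("classifier_", key, ".csv")))))
  manifest <- list(
    package = "rhythmtrack",
    version = as.character(utils::packageVersion("rhythmtrack")),
    r_version = R.version.string,
    master_seed = seed,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(participants = participants, features = features,
                 spectra_roi = spectra_roi, significance = significance,
                 group_comparisons = group_comparisons,
                 correlations = correlations, classifier_reports = reports,
                 manifest = manifest, out_dir = out_dir))
}
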