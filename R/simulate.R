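# Synthetic cohorts: stimuli, phase-locked multi-channel EEG with a von
# Mises phase-jitter model, 1/f background noise, an ocular channel, and
# clinical metadata with known ground-truth structure.

#' Default group coherence targets
#'
#' Normalized-coherence targets per band for healthy controls (HC), patients
#' with positive outcome (DOC_P), and patients with negative outcome
#' (DOC_N). The pattern encodes the study conditions the generator emulates:
#' strong 41 Hz and sideband locking in HC and DOC_P with DOC_N far lower,
#' graded low-frequency and speech-tracking responses HC > DOC_P > DOC_N.
#'
#' @return Named list of named numeric vectors (one per group).
#' @export
default_coherence_targets <- function() {
  list(
    HC    = c(coh_41 = 0.60, coh_41pm2 = 0.42, coh_2 = 0.35, coh_4 = 0.30,
              coh_delta = 0.25, coh_theta = 0.20),
    DOC_P = c(coh_41 = 0.50, coh_41pm2 = 0.38, coh_2 = 0.20, coh_4 = 0.18,
              coh_delta = 0.15, coh_theta = 0.12),
    DOC_N = c(coh_41 = 0.10, coh_41pm2 = 0.08, coh_2 = 0.15, coh_4 = 0.12,
              coh_delta = 0.10, coh_theta = 0.08)
  )
}

#' Cohort specification
#'
#' Collects every knob of the synthetic-cohort generator. Identical
#' specifications (same seed) produce identical cohorts.
#'
#' @param n_per_group Named counts for groups `HC`, `DOC_P`, `DOC_N`.
#' @param coherence_targets Named list mapping group to a named vector of
#'   band targets in \[0, 1\] (`coh_41`, `coh_41pm2`, `coh_2`, `coh_4`,
#'   `coh_delta`, `coh_theta`). An entry of length 2 is a range over which
#'   per-participant targets are spread uniformly; a scalar entry m gets
#'   multiplicative Gaussian heterogeneity with standard deviation
#'   `2 * target_jitter_sd * m` (dispersion scales with the band mean). A
#'   shared latent responsiveness factor (weight 0.9) correlates a
#'   participant's targets across bands.
#' @param noise_exponent Spectral slope of the 1/f background noise.
#' @param eog_leak Scalar gain of the ocular trace leaking into each EEG
#'   channel.
#' @param score_noise_sd Dispersion of clinical scores around their
#'   coherence-linked mean.
#' @param target_jitter_sd Half the coefficient of variation of the
#'   between-participant band-target heterogeneity (see
#'   `coherence_targets`).
#' @param n_segments Number of 2-s analysis segments per recording.
#' @param n_speech_incomplete Number of MCS participants whose speech-session
#'   data are marked incomplete (they are excluded from speech-based
#'   analyses, emulating terminated second sessions).
#' @param seed Integer master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(HC = 16, DOC_P = 15, DOC_N = 16),
                        coherence_targets = default_coherence_targets(),
                        noise_exponent = 1,
                        eog_leak = 0.05,
                        score_noise_sd = 3,
                        target_jitter_sd = 0.5,
                        n_segments = 450,
                        n_speech_incomplete = 3,
                        seed = 1) {
  stopifnot(all(c("HC", "DOC_P", "DOC_N") %in% names(n_per_group)),
            all(n_per_group >= 1), n_segments >= 2,
            target_jitter_sd >= 0, score_noise_sd >= 0)
  for (g in names(coherence_targets)) {
    v <- unlist(coherence_targets[[g]])
    if (any(v < 0 | v > 1))
      stop("coherence targets must lie in [0, 1] (group ", g, ")",
           call. = FALSE)
  }
  structure(list(
    n_per_group = n_per_group, coherence_targets = coherence_targets,
    noise_exponent = noise_exponent, eog_leak = eog_leak,
    score_noise_sd = score_noise_sd, target_jitter_sd = target_jitter_sd,
    n_segments = n_segments, n_speech_incomplete = n_speech_incomplete,
    seed = as.integer(seed)), class = "cohort_spec")
}

feature_bins <- function(feature) {
  switch(feature,
         coh_41 = 41, coh_41pm2 = c(39, 43), coh_2 = 2, coh_4 = 4,
         coh_delta = seq(0.5, 3.5, by = 0.5),
         coh_theta = seq(4, 8, by = 0.5),
         stop("unknown feature ", feature))
}

# Consciousness categories, ordered.
doc_levels <- function() c("UWS", "MCS-", "MCS+", "EMCS")

crsr_to_category <- function(crsr) {
  cut(crsr, breaks = c(-1, 9, 15, 23), labels = c("UWS", "MCS-", "MCS+"))
}

category_crsr_range <- function(cat) {
  switch(as.character(cat),
         "UWS" = c(0, 9), "MCS-" = c(10, 15), "MCS+" = c(16, 22),
         "EMCS" = c(23, 23))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw a participant metadata table (ids, groups, targets, clinical scores,
# outcome labels) for a cohort spec. Deterministic given the spec seed.
draw_participants <- function(spec) {
  groups <- rep(c("HC", "DOC_P", "DOC_N"),
                times = spec$n_per_group[c("HC", "DOC_P", "DOC_N")])
  n <- length(groups)
  feats <- c("coh_41", "coh_41pm2", "coh_2", "coh_4", "coh_delta",
             "coh_theta")
  withr::with_seed(derive_seed(spec$seed, 101), {
    # One latent responsiveness factor per participant, shared across bands
    # (weight 0.97): response strengths of one brain co-vary. Band dispersion
    # scales with the band mean (coefficient of variation 2 * jitter sd), so
    # strong responders are also the most heterogeneous.
    u <- stats::rnorm(n)
    tmat <- sapply(feats, function(fe) {
      eps <- stats::rnorm(n)
      z <- 0.97 * u + sqrt(1 - 0.97^2) * eps
      vapply(seq_len(n), function(i) {
        tg <- spec$coherence_targets[[groups[i]]][[fe]]
        if (length(tg) == 2) tg[1] + (tg[2] - tg[1]) * stats::pnorm(z[i])
        else clip(tg + 2 * spec$target_jitter_sd * tg * z[i], 0, 1)
      }, numeric(1))
    })
    tmat <- matrix(tmat, nrow = n, dimnames = list(NULL, paste0("target_", feats)))

    crsr_base <- clip(round(3 + 25 * tmat[, "target_coh_41"] +
                              stats::rnorm(n, 0, spec$score_noise_sd)), 0, 23)
    gose <- clip(round(1 + 9 * tmat[, "target_coh_41"] +
                         stats::rnorm(n, 0, spec$score_noise_sd * 0.4)), 1, 8)
    base_cat <- as.character(crsr_to_category(crsr_base))
    base_cat[groups == "HC"] <- NA

    lev <- doc_levels()
    fu_cat <- base_cat
    crsr_fu <- crsr_base
    for (i in seq_len(n)) {
      if (groups[i] == "HC") next
      pos <- match(base_cat[i], lev)
      if (groups[i] == "DOC_P") {
        step <- sample(1:2, 1, prob = c(0.7, 0.3))
        new <- min(pos + step, length(lev))
        if (new == pos) new <- pos + 1   # guarantee an advance
      } else {
        step <- sample(c(0, -1), 1, prob = c(0.7, 0.3))
        new <- max(pos + step, 1)
      }
      fu_cat[i] <- lev[new]
      rng <- category_crsr_range(lev[new])
      crsr_fu[i] <- sample(seq(rng[1], rng[2]), 1)
    }
    # DOC_N participants can never land above baseline
    outcome <- ifelse(groups == "HC", NA,
                      ifelse(match(fu_cat, lev) > match(base_cat, lev),
                             "positive", "negative"))
    diagnosis <- ifelse(groups == "HC", "HC",
                        ifelse(base_cat == "UWS", "UWS", "MCS"))

    speech_complete <- rep(TRUE, n)
    mcs_idx <- which(diagnosis == "MCS")
    k <- min(spec$n_speech_incomplete, length(mcs_idx))
    if (k > 0)
      speech_complete[sample(mcs_idx, k)] <- FALSE

    dplyr::bind_cols(
      tibble::tibble(
        id = sprintf("P%03d", seq_len(n)),
        cohort_group = groups,
        group = diagnosis,
        baseline_category = base_cat,
        followup_category = fu_cat,
        crsr_baseline = as.numeric(crsr_base),
        crsr_followup = as.numeric(crsr_fu),
        gose = as.numeric(gose),
        outcome = outcome,
        speech_complete = speech_complete),
      tibble::as_tibble(tmat))
  })
}

#' Simulate one multi-channel EEG recording
#'
#' Each EEG channel is a sum of phase-locked sinusoids, 1/f background
#' noise, and a leaked ocular trace:
#' \deqn{x(t) = \sum_f A w_{ch} \cos(2\pi f \tau + \beta_{fs} + j_s)
#'   + \mathrm{pink} + \lambda \cdot \mathrm{EOG}}
#' where \eqn{\tau} is time within the 2-s segment s, \eqn{\beta_{fs}} the
#' stimulus reference phase, and the segmentwise jitter \eqn{j_s} is von
#' Mises with concentration chosen (via [vm_kappa()]) so the realized
#' normalized coherence approaches the target as the segment count grows.
#' The sinusoid gain peaks at the centro-frontal labels.
#'
#' @param stim A `stimulus_track` defining duration and reference phases.
#' @param channel_labels Channel set; must contain the 14 centro-frontal
#'   labels and the EOG label.
#' @param coherence_by_channel Tibble with columns `channel`, `freq_hz`,
#'   `target` (targets in \[0, 1\]).
#' @param noise_exponent 1/f slope of the background noise.
#' @param eog_leak Gain of the ocular trace in EEG channels.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @param eog_label Ocular channel label.
#' @param amplitude Locked-sinusoid amplitude (microvolts) at ROI channels.
#' @param noise_sd Background-noise standard deviation (microvolts); 0
#'   disables noise.
#' @param participant_id,session Metadata stored in the recording.
#' @param jitter Optional precomputed per-(channel, freq) jitter list, used
#'   to share response phases across sessions; normally left NULL.
#' @return An `eeg_recording`.
#' @export
simulate_recording <- function(stim, channel_labels = c(roi_centrofrontal(), "EOG"),
                               coherence_by_channel = NULL,
                               noise_exponent = 1, eog_leak = 0.05,
                               rate = 100, seed = 1, eog_label = "EOG",
                               amplitude = 2, noise_sd = 1,
                               participant_id = NA_character_, session = 1L,
                               jitter = NULL) {
  if (!all(roi_centrofrontal() %in% channel_labels) ||
      !eog_label %in% channel_labels)
    stop("channel set must include the 14 centro-frontal labels and '",
         eog_label, "'", call. = FALSE)
  if (!is.null(coherence_by_channel)) {
    bad <- setdiff(unique(coherence_by_channel$channel), channel_labels)
    if (length(bad) > 0)
      stop("unknown channel label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(coherence_by_channel$target < 0 | coherence_by_channel$target > 1))
      stop("coherence targets must lie in [0, 1]", call. = FALSE)
  }
  duration <- stim$duration
  n <- round(duration * rate)
  nper <- 2 * rate
  n_seg <- n %/% nper
  tau <- rep((seq_len(nper) - 1) / rate, n_seg)

  ref <- stim$reference_phases
  ref_freqs <- as.numeric(rownames(ref))

  withr::with_seed(seed, {
    eog <- 30 * pink_noise(n, 1.5)
    data <- matrix(0, nrow = length(channel_labels), ncol = n,
                   dimnames = list(channel_labels, NULL))
    for (ch in channel_labels) {
      if (ch == eog_label) {
        data[ch, ] <- eog
        next
      }
      x <- if (noise_sd > 0) noise_sd * pink_noise(n, noise_exponent) else
        numeric(n)
      x <- x + eog_leak * eog
      w <- if (ch %in% roi_centrofrontal()) 1 else 0.6
      if (!is.null(coherence_by_channel)) {
        rows <- coherence_by_channel[coherence_by_channel$channel == ch, ]
        for (r in seq_len(nrow(rows))) {
          f <- rows$freq_hz[r]; tg <- rows$target[r]
          if (tg <= 0) next
          j <- if (!is.null(jitter)) jitter[[ch]][[as.character(f)]] else
            rvonmises(n_seg, 0, vm_kappa(tg))
          ri <- which(abs(ref_freqs - f) < 1e-9)
          beta <- if (length(ri) == 1) ref[ri, seq_len(n_seg)] else
            rep(0, n_seg)
          ph <- rep(beta + j, each = nper)
          x <- x + amplitude * w * cos(2 * pi * f * tau + ph)
        }
      }
      data[ch, ] <- x
    }
    eeg_recording(data, rate = rate, labels = channel_labels,
                  eog_label = eog_label, participant_id = participant_id,
                  session = session, reference = "FCz")
  })
}

# Expand a participant's band targets into a (channel, freq_hz, target)
# grid for one condition.
targets_grid <- function(target_row, condition, channels,
                         eog_label = "EOG") {
  feats <- if (condition == "tone") c("coh_2", "coh_4", "coh_41pm2", "coh_41")
  else c("coh_delta", "coh_theta")
  grid <- purrr::map(feats, function(fe) {
    tibble::tibble(freq_hz = feature_bins(fe),
                   target = target_row[[paste0("target_", fe)]])
  }) |> dplyr::bind_rows() |>
    dplyr::distinct(.data$freq_hz, .keep_all = TRUE)
  tidyr::expand_grid(channel = setdiff(channels, eog_label), grid)
}

#' Simulate the recordings of one participant
#'
#' Generates the tone recording (one session) and, when requested, the two
#' speech-condition sessions. The two speech sessions share the same
#' segmentwise response phases (the stimulus-locked response is assumed
#' reproducible across presentations) but have independent noise, so
#' cross-session averaging improves the signal-to-noise ratio without
#' changing the coherence target.
#'
#' @param participant One row of the participants table.
#' @param spec The `cohort_spec`.
#' @param stimuli Named list with elements `tone` and/or `speech`.
#' @param conditions Character subset of `c("tone", "speech")`.
#' @param channel_labels Channel set.
#' @param rate Sampling rate in Hz.
#' @return Named list of recordings: `tone` (one recording) and `speech`
#'   (list of two sessions).
#' @export
simulate_participant_recordings <- function(participant, spec, stimuli,
                                            conditions = c("tone", "speech"),
                                            channel_labels = c(roi_centrofrontal(), "EOG"),
                                            rate = 100) {
  idx <- as.integer(sub("P", "", participant$id))
  out <- list()
  if ("tone" %in% conditions) {
    grid <- targets_grid(participant, "tone", channel_labels)
    out$tone <- simulate_recording(
      stimuli$tone, channel_labels, grid,
      noise_exponent = spec$noise_exponent, eog_leak = spec$eog_leak,
      rate = rate, seed = derive_seed(spec$seed, 1000 + idx),
      participant_id = participant$id, session = 1L)
  }
  if ("speech" %in% conditions) {
    grid <- targets_grid(participant, "speech", channel_labels)
    n_seg <- round(stimuli$speech$duration / 2)
    jit <- withr::with_seed(derive_seed(spec$seed, 2000 + idx), {
      chs <- setdiff(channel_labels, "EOG")
      stats::setNames(lapply(chs, function(ch) {
        rows <- grid[grid$channel == ch, ]
        js <- lapply(seq_len(nrow(rows)), function(r)
          rvonmises(n_seg, 0, vm_kappa(rows$target[r])))
        stats::setNames(js, as.character(rows$freq_hz))
      }), chs)
    })
    out$speech <- lapply(1:2, function(s) {
      simulate_recording(
        stimuli$speech, channel_labels, grid,
        noise_exponent = spec$noise_exponent, eog_leak = spec$eog_leak,
        rate = rate, seed = derive_seed(spec$seed, 3000 + 2L * idx + s),
        participant_id = participant$id, session = s, jitter = jit)
    })
  }
  out
}

#' Simulate a cohort
#'
#' Generates participant metadata (groups, consciousness categories, CRS-R
#' and GOS-E scores linked to the 41 Hz coherence target, outcome labels)
#' and either full waveform recordings (`mode = "waveform"`) or band
#' features drawn directly from the von Mises phase model
#' (`mode = "features"`). The features mode samples the very phase draws the
#' waveform path would embed in the EEG and reduces them to normalized
#' coherence, skipping waveform rendering; it is the same generative model
#' one level up and is intended for many-replicate power and calibration
#' studies.
#'
#' @param spec A `cohort_spec`.
#' @param mode `"features"` or `"waveform"`.
#' @param conditions For waveform mode, which stimuli to render.
#' @return For `"features"`: list with `participants` (metadata tibble) and
#'   `features` (one row per participant: `coh_41`, `coh_41pm2`, `coh_2`,
#'   `coh_4`, `coh_delta`, `coh_theta`, joined with metadata). For
#'   `"waveform"`: list with `participants`, `stimuli`, and `recordings`
#'   (per-participant lists from [simulate_participant_recordings()]).
#' @examples
#' spec <- cohort_spec(n_per_group = c(HC = 3, DOC_P = 3, DOC_N = 3),
#'                     n_segments = 50, seed = 7)
#' coh <- simulate_cohort(spec)
#' coh$features[, c("id", "group", "coh_41")]
#' @export
simulate_cohort <- function(spec, mode = c("features", "waveform"),
                            conditions = c("tone", "speech")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "cohort_spec"))
  participants <- draw_participants(spec)
  if (mode == "features") {
    feats <- c("coh_41", "coh_41pm2", "coh_2", "coh_4", "coh_delta",
               "coh_theta")
    rows <- purrr::map(seq_len(nrow(participants)), function(i) {
      withr::with_seed(derive_seed(spec$seed, 500 + i), {
        vals <- vapply(feats, function(fe) {
          tg <- participants[[paste0("target_", fe)]][i]
          bins <- feature_bins(fe)
          mean(vapply(bins, function(b) {
            th <- rvonmises(spec$n_segments, 0, vm_kappa(tg))
            sqrt(sum(cos(th))^2 + sum(sin(th))^2) / spec$n_segments
          }, numeric(1)))
        }, numeric(1))
        tibble::as_tibble(as.list(vals))
      })
    })
    features <- dplyr::bind_cols(participants, dplyr::bind_rows(rows))
    return(list(participants = participants, features = features))
  }
  duration <- spec$n_segments * 2
  stimuli <- list()
  if ("tone" %in% conditions)
    stimuli$tone <- make_modulated_tone(duration)
  if ("speech" %in% conditions)
    stimuli$speech <- make_speech_envelope(duration, rate = 100,
                                           seed = derive_seed(spec$seed, 11))
  recordings <- lapply(seq_len(nrow(participants)), function(i) {
    simulate_participant_recordings(participants[i, ], spec, stimuli,
                                    conditions = conditions)
  })
  names(recordings) <- participants$id
  list(participants = participants, stimuli = stimuli,
       recordings = recordings)
}

#' Score-noise dispersion for a target correlation
#'
#' For clinical scores generated as `score = intercept + slope * target +
#' noise`, returns the Gaussian noise sd that yields a population
#' correlation `rho` between score and target, given the sd of the targets.
#'
#' @param rho Desired correlation in (0, 1).
#' @param target_sd Standard deviation of the coherence targets.
#' @param slope Slope of the affine score map (25 for CRS-R, 9 for GOS-E).
#' @return Noise standard deviation.
#' @export
score_noise_sd_for_rho <- function(rho, target_sd, slope = 25) {
  stopifnot(rho > 0, rho < 1, target_sd > 0)
  slope * target_sd * sqrt(1 / rho^2 - 1)
}
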