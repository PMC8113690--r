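# Cerebro-acoustic phase coherence: segmented DFT phases, the coherence
# statistic and its ITPC reduction, centro-frontal band features, and signed
# response topographies.

#' Centro-frontal region of interest
#'
#' The 14 centro-frontal electrodes of the international 10-20 system over
#' which phase coherence is strongest and which are used for group
#' comparisons, correlations, and classification.
#'
#' @return Character vector of 14 channel labels.
#' @export
roi_centrofrontal <- function() {
  c("Fz", "F1", "F2", "F3", "F4", "FC1", "FC2", "FC3", "FC4",
    "Cz", "C1", "C2", "C3", "C4")
}

#' Segmented DFT phases of a single channel
#'
#' Splits a signal into non-overlapping `bin_s`-second bins, applies the
#' discrete Fourier transform to each, and returns the phase at every
#' frequency bin strictly between 0 Hz and the Nyquist frequency. With the
#' default 2-s bins the grid has 0.5 Hz resolution. A trailing partial bin
#' is discarded.
#'
#' @param x Numeric signal (one channel).
#' @param rate Sampling rate in Hz.
#' @param bin_s Bin length in seconds (default 2).
#' @return A frequency-by-segment matrix of phases in (-pi, pi]; rownames
#'   are frequencies in Hz, and the numeric grid is in `attr(, "freqs")`.
#' @examples
#' ph <- segment_phases(cos(2 * pi * 41 * seq(0, 10, by = 0.01)[-1]), rate = 100)
#' dim(ph) # 99 frequencies x 5 segments
#' @export
segment_phases <- function(x, rate = 100, bin_s = 2) {
  nper <- round(rate * bin_s)
  n_seg <- floor(length(x) / nper)
  if (n_seg < 1)
    stop("signal shorter than one analysis bin", call. = FALSE)
  X <- matrix(x[seq_len(nper * n_seg)], nrow = nper)
  spec <- stats::mvfft(X)
  k <- seq_len(nper / 2 - 1)
  freqs <- k / bin_s
  ph <- Arg(spec[k + 1, , drop = FALSE])
  dimnames(ph) <- list(as.character(freqs), NULL)
  attr(ph, "freqs") <- freqs
  ph
}

#' Phase coherence between response and stimulus phases
#'
#' For each frequency bin f, forms the phase differences
#' \eqn{\alpha_{ft} - \beta_{ft}} between the response phase and the stimulus
#' phase across the T analysis segments and sums their unit phasors. The
#' magnitude of that sum is the resultant \eqn{R_f}; the package reports
#' \itemize{
#'   \item `resultant` — \eqn{R_f \in [0, T]},
#'   \item `coherence_norm` — \eqn{R_f / T \in [0, 1]}, the normalized phase
#'     coherence (the primary quantity, comparable across recordings),
#'   \item `rayleigh_z` — \eqn{R_f^2 / T}, the Rayleigh test statistic; a
#'     value above 3 rejects phase uniformity at P < 0.05,
#'   \item `mean_phase` — the circular mean of the phase differences.
#' }
#'
#' @param eeg_phases,stim_phases Frequency-by-segment phase matrices of equal
#'   shape (see [segment_phases()]).
#' @return A tibble with one row per frequency: `freq_hz`, `n_segments`,
#'   `resultant`, `coherence_norm`, `rayleigh_z`, `mean_phase`.
#' @examples
#' a <- matrix(rep(0.3, 10), nrow = 1, dimnames = list("41", NULL))
#' attr(a, "freqs") <- 41
#' phase_coherence(a, a * 0) # perfect locking: coherence_norm = 1
#' @export
phase_coherence <- function(eeg_phases, stim_phases) {
  if (!all(dim(eeg_phases) == dim(stim_phases)))
    stop("response and stimulus phase matrices must have the same shape",
         call. = FALSE)
  T_seg <- ncol(eeg_phases)
  if (T_seg < 2)
    stop("at least 2 segments are required", call. = FALSE)
  d <- eeg_phases - stim_phases
  sum_cos <- unname(rowSums(cos(d)))
  sum_sin <- unname(rowSums(sin(d)))
  resultant <- sqrt(sum_cos^2 + sum_sin^2)
  freqs <- attr(eeg_phases, "freqs")
  if (is.null(freqs)) freqs <- as.numeric(rownames(eeg_phases))
  tibble::tibble(
    freq_hz = freqs,
    n_segments = T_seg,
    resultant = resultant,
    coherence_norm = resultant / T_seg,
    rayleigh_z = resultant^2 / T_seg,
    mean_phase = atan2(sum_sin, sum_cos)
  )
}

#' Inter-trial phase coherence
#'
#' The special case of [phase_coherence()] for a periodic stimulus: when the
#' stimulus repeats exactly within every analysis bin its phase is constant,
#' and by rotation invariance the coherence equals the resultant of the
#' response phases alone (stimulus phase taken as zero).
#'
#' @param eeg_phases Frequency-by-segment phase matrix.
#' @return Same tibble as [phase_coherence()].
#' @export
itpc <- function(eeg_phases) {
  phase_coherence(eeg_phases, array(0, dim = dim(eeg_phases)))
}

#' Coherence spectrum of a recording
#'
#' Computes the cerebro-acoustic phase-coherence spectrum of every EEG
#' channel (the EOG channel is skipped) against a stimulus. For a modulated
#' tone — whose 0.5 s period divides the 2 s bin, making the stimulus phase
#' constant — the ITPC reduction is used over the full frequency grid. For a
#' speech envelope the stimulus phases are the envelope's own segmented DFT
#' phases, computed over the same bins.
#'
#' @param rec An `eeg_recording` at the 100 Hz analysis rate.
#' @param stim A `stimulus_track`.
#' @param condition Label stored in the result (defaults to the stimulus
#'   kind).
#' @return A `coherence_spectrum` tibble: one row per channel x frequency
#'   with the columns of [phase_coherence()] plus `channel`, `condition`,
#'   and `participant_id`.
#' @export
compute_coherence <- function(rec, stim, condition = stim$kind) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(stim, "stimulus_track"))
  eeg_ch <- setdiff(rec$labels, rec$eog_label)
  stim_phases <- NULL
  if (stim$kind == "speech") {
    env <- stim$samples
    if (stim$rate != rec$rate)
      stop("stimulus and recording rates differ", call. = FALSE)
    stim_phases <- segment_phases(env, rate = rec$rate, bin_s = 2)
  }
  out <- purrr::map(eeg_ch, function(ch) {
    ph <- segment_phases(rec$data[ch, ], rate = rec$rate, bin_s = 2)
    if (is.null(stim_phases)) {
      res <- itpc(ph)
    } else {
      n_seg <- min(ncol(ph), ncol(stim_phases))
      res <- phase_coherence(ph[, seq_len(n_seg), drop = FALSE],
                             stim_phases[, seq_len(n_seg), drop = FALSE])
    }
    res$channel <- ch
    res
  })
  out <- dplyr::bind_rows(out) |>
    dplyr::mutate(condition = condition,
                  participant_id = rec$participant_id %||% NA_character_) |>
    dplyr::select("participant_id", "condition", "channel",
                  dplyr::everything())
  class(out) <- c("coherence_spectrum", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Band features from a coherence spectrum
#'
#' Reduces a coherence spectrum to the six features used for group
#' comparison, correlation, and classification: the region-of-interest mean
#' of the normalized coherence at 41 Hz, at the 39/43 Hz sidebands
#' (averaged, "41 +/- 2 Hz"), at 2 and 4 Hz, and over the delta
#' (\[0.5, 4) Hz) and theta (\[4, 8\] Hz) bands. Delta is half-open so the
#' 4 Hz bin counts toward theta only.
#'
#' @param spec A `coherence_spectrum` tibble (may hold several participants
#'   and conditions; features are computed within each).
#' @param roi Channel labels to average over; defaults to the 14-channel
#'   centro-frontal set.
#' @return A tibble with one row per participant x condition and columns
#'   `coh_41`, `coh_41pm2`, `coh_2`, `coh_4`, `coh_delta`, `coh_theta`.
#' @export
band_features <- function(spec, roi = roi_centrofrontal()) {
  if (length(roi) == 0) stop("empty ROI", call. = FALSE)
  missing_ch <- setdiff(roi, unique(spec$channel))
  if (length(missing_ch) > 0)
    stop("ROI channels absent from spectrum: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  need <- c(2, 4, 39, 41, 43)
  if (!all(need %in% spec$freq_hz))
    stop("required frequency bins missing: ",
         paste(setdiff(need, spec$freq_hz), collapse = ", "), call. = FALSE)
  bin_mean <- function(coh, f, sel) mean(coh[sel])
  spec |>
    dplyr::filter(.data$channel %in% roi) |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(
      coh_41 = mean(.data$coherence_norm[.data$freq_hz == 41]),
      coh_41pm2 = mean(.data$coherence_norm[.data$freq_hz %in% c(39, 43)]),
      coh_2 = mean(.data$coherence_norm[.data$freq_hz == 2]),
      coh_4 = mean(.data$coherence_norm[.data$freq_hz == 4]),
      coh_delta = mean(.data$coherence_norm[.data$freq_hz >= 0.5 &
                                              .data$freq_hz < 4]),
      coh_theta = mean(.data$coherence_norm[.data$freq_hz >= 4 &
                                              .data$freq_hz <= 8]),
      .groups = "drop"
    )
}

#' Signed coherence topography
#'
#' For topographic display the (always positive) coherence is given a sign
#' describing the phase relationship to a reference electrode: a channel
#' whose mean response phase differs from the reference's by more than 90
#' degrees is negated; 90 degrees exactly keeps the positive sign. Channels
#' with an undefined mean phase (zero resultant) are kept positive with a
#' warning.
#'
#' @param spec A `coherence_spectrum` for a single participant/condition.
#' @param frequency Frequency bin in Hz.
#' @param reference Reference channel label (default `"Fz"`).
#' @return A `signed_topography` tibble: `channel`, `coherence`,
#'   `signed_coherence`, with the frequency, reference, and normalizer (NA
#'   until [normalize_topography()]) as attributes.
#' @export
signed_topography <- function(spec, frequency, reference = "Fz") {
  sl <- dplyr::filter(spec, .data$freq_hz == frequency)
  if (nrow(sl) == 0)
    stop("frequency ", frequency, " Hz not present in spectrum", call. = FALSE)
  if (!reference %in% sl$channel)
    stop("reference channel ", reference, " not present", call. = FALSE)
  ref_phase <- sl$mean_phase[sl$channel == reference][1]
  undef <- sl$resultant < 1e-12
  if (any(undef))
    warning("mean phase undefined (zero resultant) for: ",
            paste(sl$channel[undef], collapse = ", "),
            "; sign forced positive")
  dist <- circ_dist(sl$mean_phase, ref_phase)
  sgn <- ifelse(!undef & dist > pi / 2, -1, 1)
  sgn[sl$channel == reference] <- 1
  out <- tibble::tibble(channel = sl$channel,
                        coherence = sl$coherence_norm,
                        signed_coherence = sl$coherence_norm * sgn)
  structure(out, frequency = frequency, reference = reference,
            normalizer = NA_real_,
            class = c("signed_topography", class(out)))
}

#' Normalize a signed topography
#'
#' Divides every signed value by the 95th percentile of the absolute
#' coherence across electrodes, so that topographies of groups with very
#' different response strengths are displayed on a comparable scale. The
#' normalizer is stored in the result's attributes.
#'
#' @param topo A `signed_topography`.
#' @return The topography with `signed_coherence` (and `coherence`) divided
#'   by the 95th percentile; attribute `normalizer` records the divisor.
#' @export
normalize_topography <- function(topo) {
  stopifnot(inherits(topo, "signed_topography"))
  if (nrow(topo) < 2) stop("need at least 2 channels", call. = FALSE)
  q <- stats::quantile(abs(topo$signed_coherence), 0.95, names = FALSE)
  if (q <= 0) stop("normalizer is zero; all coherences vanish", call. = FALSE)
  topo$signed_coherence <- topo$signed_coherence / q
  topo$coherence <- topo$coherence / q
  attr(topo, "normalizer") <- q
  topo
}
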