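# Signal conditioning: zero-phase FIR low-pass + decimation, EOG regression,
# common-average re-referencing, cross-session averaging. The pipeline order
# is fixed: filter/downsample -> EOG regression -> re-reference -> averaging.

# Zero-phase application of a symmetric (linear-phase, odd-length) FIR
# kernel via FFT convolution with edge-reflection padding.
apply_fir_zero_phase <- function(x, h) {
  m <- (length(h) - 1) / 2
  n <- length(x)
  pad_l <- x[pmin(m:1 + 1, n)]
  pad_r <- x[pmax(n - (1:m), 1)]
  xp <- c(pad_l, x, pad_r)
  L <- length(xp) + length(h) - 1
  nfft <- stats::nextn(L, 2)
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, nfft - length(xp)))) *
                       stats::fft(c(h, rep(0, nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[(2 * m + 1):(2 * m + n)]
}

# Kaiser-window FIR low-pass spanning `span_s` seconds of signal at `rate`.
# The -6 dB cutoff sits between the 45 Hz passband edge and the 50 Hz
# Nyquist of the 100 Hz target rate.
design_antialias_fir <- function(rate, span_s = 0.2, cutoff = 47.5,
                                 beta = 3) {
  n_taps <- round(span_s * rate)
  if (n_taps %% 2 == 1) n_taps <- n_taps + 1   # even order -> odd length
  h <- as.numeric(signal::fir1(n_taps, cutoff / (rate / 2), type = "low",
                               window = signal::kaiser(n_taps + 1, beta)))
  h / sum(h)   # exact unity gain at DC
}

# Magnitude response of a FIR kernel at the given frequencies.
fir_response <- function(h, freqs, rate) {
  k <- seq_along(h) - 1
  vapply(freqs, function(f) {
    Mod(sum(h * exp(-1i * 2 * pi * f * k / rate)))
  }, numeric(1))
}

#' Low-pass filter and downsample to 100 Hz
#'
#' Applies a zero-phase anti-aliasing FIR low-pass (Kaiser window spanning
#' 200 ms of the input rate, passband to 45 Hz) and decimates to 100 Hz.
#' Output length is `floor(input length / factor)`.
#'
#' @param rec An `eeg_recording` whose rate is a multiple of 100 Hz
#'   (typically 1000 Hz).
#' @param cutoff FIR -6 dB cutoff in Hz.
#' @param beta Kaiser window shape parameter.
#' @return The filtered recording resampled to 100 Hz.
#' @export
lowpass_downsample <- function(rec, cutoff = 47.5, beta = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate %% 100 != 0)
    stop("sampling rate must be divisible by 100 Hz", call. = FALSE)
  factor <- rec$rate / 100
  h <- design_antialias_fir(rec$rate, cutoff = cutoff, beta = beta)
  n_out <- floor(ncol(rec$data) / factor)
  keep <- seq(1, by = factor, length.out = n_out)
  filt <- t(apply(rec$data, 1, apply_fir_zero_phase, h = h))
  rec$data <- filt[, keep, drop = FALSE]
  rownames(rec$data) <- rec$labels
  rec$rate <- 100
  rec
}

#' Regress the EOG channel out of every EEG channel
#'
#' Replaces each EEG channel by its residual after ordinary least-squares
#' projection onto the EOG channel (with intercept), removing ocular
#' artifacts that leak linearly into the scalp channels. Residuals have zero
#' sample covariance with the EOG trace. Applied before re-referencing so
#' ocular signal is not spread through the common average.
#'
#' @param rec An `eeg_recording` with a non-constant EOG channel.
#' @return The recording with cleaned EEG channels (EOG kept unchanged).
#' @export
regress_out_eog <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  eog <- rec$data[rec$eog_label, ]
  if (stats::sd(eog) == 0)
    stop("EOG channel is constant; regression design is singular",
         call. = FALSE)
  eeg_ch <- setdiff(rec$labels, rec$eog_label)
  X <- cbind(1, eog)
  fit <- stats::lm.fit(X, t(rec$data[eeg_ch, , drop = FALSE]))
  rec$data[eeg_ch, ] <- t(fit$residuals)
  rec
}

#' Re-reference to the common average
#'
#' Subtracts the per-sample mean of all EEG channels (the EOG channel is
#' excluded from the average and left untouched), converting the online FCz
#' reference to a common average reference.
#'
#' @param rec An `eeg_recording` with at least 2 EEG channels.
#' @return The re-referenced recording, `reference = "common_average"`.
#' @export
rereference_common_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  eeg_ch <- setdiff(rec$labels, rec$eog_label)
  if (length(eeg_ch) < 2)
    stop("need at least 2 non-EOG channels", call. = FALSE)
  avg <- colMeans(rec$data[eeg_ch, , drop = FALSE])
  rec$data[eeg_ch, ] <- sweep(rec$data[eeg_ch, , drop = FALSE], 2, avg)
  rec$reference <- "common_average"
  rec
}

#' Average two sessions of the same stimulus
#'
#' Stimulus-locked responses are expected to repeat across presentations of
#' the same material, so recordings from the two sessions are averaged
#' sample-wise (aligned to stimulus onset). Lengths may differ; the longer
#' recording is trimmed to the shorter.
#'
#' @param rec1,rec2 `eeg_recording`s with identical labels and rate.
#' @return The averaged recording (session set to 1).
#' @export
average_sessions <- function(rec1, rec2) {
  stopifnot(inherits(rec1, "eeg_recording"), inherits(rec2, "eeg_recording"))
  if (!identical(rec1$labels, rec2$labels))
    stop("channel labels differ between sessions", call. = FALSE)
  if (rec1$rate != rec2$rate)
    stop("sampling rates differ between sessions", call. = FALSE)
  n <- min(ncol(rec1$data), ncol(rec2$data))
  rec1$data <- (rec1$data[, seq_len(n), drop = FALSE] +
                  rec2$data[, seq_len(n), drop = FALSE]) / 2
  rec1$session <- 1L
  rec1
}

#' Full preprocessing chain
#'
#' Applies, in fixed order: anti-alias filtering and downsampling to 100 Hz
#' (skipped when the recording is already at 100 Hz), EOG regression, and
#' common-average re-referencing.
#'
#' @param rec An `eeg_recording`.
#' @return The preprocessed recording at 100 Hz.
#' @export
preprocess_recording <- function(rec) {
  if (rec$rate > 100) rec <- lowpass_downsample(rec)
  rec <- regress_out_eog(rec)
  rereference_common_average(rec)
}
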