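# Stimulus construction: an amplitude- and frequency-modulated tone and a
# synthetic speech-like envelope, each carrying the stimulus reference phases
# used by the cerebro-acoustic coherence computation.

new_stimulus_track <- function(samples, rate, kind, reference_phases,
                               duration) {
  structure(
    list(samples = samples, rate = rate, kind = kind,
         reference_phases = reference_phases, duration = duration),
    class = "stimulus_track"
  )
}

#' @export
print.stimulus_track <- function(x, ...) {
  cat(sprintf("<stimulus_track: %s, %.0f s at %g Hz, %d reference frequencies>\n",
              x$kind, x$duration, x$rate, nrow(x$reference_phases)))
  invisible(x)
}

n_segments_of <- function(duration, bin_s = 2) as.integer(duration / bin_s)

#' Modulated tone stimulus
#'
#' Builds a pure-tone carrier that is sinusoidally amplitude modulated (AM)
#' and sinusoidally frequency modulated (FM), the standard stimulus for
#' eliciting the 40 Hz auditory steady-state response. The defaults modulate
#' at 41 Hz (AM) and 2 Hz (FM) so that responses are expected at 2 and 4 Hz
#' (FM fundamental and harmonic), at 41 Hz (AM), and at the 39/43 Hz
#' intermodulation sidebands.
#'
#' The waveform is
#' \deqn{x(t) = [1 + d \sin(2\pi f_{am} t)] \sin(2\pi f_c t +
#'   (\Delta f / f_{fm}) \sin(2\pi f_{fm} t))}
#' with AM depth \eqn{d} and FM deviation \eqn{\Delta f}.
#'
#' Reference phases are the phases of the analytic modulation components at
#' each 2-s segment start, in the cosine convention of the discrete Fourier
#' transform: the AM and FM modulators are sines, so their fundamental phases
#' are \eqn{-\pi/2}; harmonics of the FM modulator get multiples of that
#' phase and sidebands the sum/difference \eqn{\phi_{am} \pm \phi_{fm}},
#' wrapped into \eqn{(-\pi, \pi]}. Because the composite stimulus period
#' (0.5 s) divides the 2-s analysis bin, every reference phase is constant
#' across segments.
#'
#' @param duration Stimulus duration in seconds; must be a multiple of 2 s.
#' @param rate Sampling rate in Hz.
#' @param carrier Carrier frequency in Hz.
#' @param am_freq,am_depth AM frequency (Hz) and depth in \[0, 1\].
#' @param fm_freq,fm_dev FM frequency (Hz) and frequency deviation (Hz);
#'   `fm_dev` must be below the carrier.
#' @return A `stimulus_track` with `kind = "modulated_tone"` and
#'   `reference_phases`, a frequency-by-segment matrix (rownames are
#'   frequencies in Hz). Frequencies whose modulation component is absent
#'   (zero AM depth or zero FM deviation) are omitted.
#' @examples
#' stim <- make_modulated_tone(duration = 4)
#' rownames(stim$reference_phases)
#' @export
make_modulated_tone <- function(duration, rate = 4000, carrier = 500,
                                am_freq = 41, am_depth = 1,
                                fm_freq = 2, fm_dev = 20) {
  if (duration <= 0 || duration %% 2 != 0)
    stop("`duration` must be a positive multiple of 2 s", call. = FALSE)
  if (am_depth < 0 || am_depth > 1)
    stop("`am_depth` must lie in [0, 1]", call. = FALSE)
  if (fm_dev >= carrier)
    stop("`fm_dev` must be smaller than the carrier frequency", call. = FALSE)
  if (carrier + am_freq + fm_dev >= rate / 2)
    stop("carrier plus modulation bandwidth must stay below the Nyquist ",
         "frequency", call. = FALSE)
  stopifnot(rate > 0, am_freq > 0, fm_freq > 0, fm_dev >= 0)

  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  fm_arg <- if (fm_dev > 0) (fm_dev / fm_freq) * sin(2 * pi * fm_freq * t) else 0
  x <- (1 + am_depth * sin(2 * pi * am_freq * t)) *
    sin(2 * pi * carrier * t + fm_arg)

  phi_fm <- -pi / 2   # sin modulator in cosine convention
  phi_am <- -pi / 2
  freqs <- numeric(0); phases <- numeric(0)
  if (fm_dev > 0) {
    freqs <- c(freqs, fm_freq, 2 * fm_freq)
    phases <- c(phases, phi_fm, wrap_phase(2 * phi_fm))
  }
  if (am_depth > 0) {
    freqs <- c(freqs, am_freq)
    phases <- c(phases, phi_am)
  }
  if (am_depth > 0 && fm_dev > 0) {
    freqs <- c(freqs, am_freq - fm_freq, am_freq + fm_freq)
    phases <- c(phases, wrap_phase(phi_am - phi_fm), wrap_phase(phi_am + phi_fm))
  }
  ord <- order(freqs)
  n_seg <- n_segments_of(duration)
  ref <- matrix(rep(phases[ord], n_seg), nrow = length(freqs),
                dimnames = list(as.character(freqs[ord]), NULL))
  new_stimulus_track(x, rate, "modulated_tone", ref, duration)
}

#' Synthetic speech-like envelope
#'
#' Generates a positive-valued, band-limited (0.3-10 Hz) noise envelope with
#' 1/f spectral weighting as a stand-in for the broadband temporal envelope
#' of narrated speech. It carries the slow (delta/theta-band) fluctuations
#' that cortical speech tracking follows; it does not model linguistic
#' content.
#'
#' Reference phases are taken from the envelope's own segmented DFT at every
#' 0.5 Hz bin in \[0.5, 10\] Hz, matching the analysis segmentation.
#'
#' @param duration Duration in seconds; multiple of 2 s.
#' @param rate Sampling rate in Hz (the analysis rate, default 100).
#' @param seed Integer seed; identical seeds give identical envelopes.
#' @return A `stimulus_track` with `kind = "speech"`.
#' @examples
#' env <- make_speech_envelope(duration = 10, seed = 1)
#' min(env$samples) >= 0
#' @export
make_speech_envelope <- function(duration, rate = 100, seed = 1) {
  if (duration <= 0 || duration %% 2 != 0)
    stop("`duration` must be a positive multiple of 2 s", call. = FALSE)
  stopifnot(rate >= 25)
  n <- round(duration * rate)
  x <- withr::with_seed(seed, {
    nf <- floor(n / 2)
    f <- seq_len(nf) * rate / n
    amp <- ifelse(f >= 0.3 & f <= 10, f^(-0.5), 0)
    spec <- complex(real = stats::rnorm(nf) * amp,
                    imaginary = stats::rnorm(nf) * amp)
    full <- complex(length.out = n)
    full[2:(nf + 1)] <- spec
    if (n %% 2 == 0) {
      full[nf + 1] <- complex(real = Re(full[nf + 1]), imaginary = 0)
      full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
    } else {
      full[(nf + 2):n] <- Conj(spec[nf:1])
    }
    Re(stats::fft(full, inverse = TRUE)) / n
  })
  x <- x / stats::sd(x)
  x <- x - min(x)            # shift so the envelope is non-negative

  ph <- segment_phases(x, rate = rate, bin_s = 2)
  keep <- as.numeric(rownames(ph)) >= 0.5 & as.numeric(rownames(ph)) <= 10
  new_stimulus_track(x, rate, "speech", ph[keep, , drop = FALSE], duration)
}
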