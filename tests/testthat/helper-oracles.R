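# Independent oracles used to pin expected values. These deliberately use
# naive loop-based implementations, not the package's vectorized paths.

# Resultant / coherence by explicit two-loop summation of the phase
# differences.
oracle_coherence <- function(eeg_phases, stim_phases) {
  nf <- nrow(eeg_phases); nt <- ncol(eeg_phases)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    sc <- 0; ss <- 0
    for (t in seq_len(nt)) {
      d <- eeg_phases[f, t] - stim_phases[f, t]
      sc <- sc + cos(d)
      ss <- ss + sin(d)
    }
    out[f] <- sqrt(sc^2 + ss^2)
  }
  out
}

# Direct DFT (explicit complex sum, no FFT) of one segment at bin k.
oracle_dft_phase <- function(x, k) {
  n <- length(x)
  idx <- 0:(n - 1)
  Arg(sum(x * exp(-2i * pi * k * idx / n)))
}

# Analytic signal via frequency-domain Hilbert weights.
oracle_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Benjamini-Hochberg step-up executed literally.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= alpha * seq_len(m) / m)
  reject <- logical(m)
  if (length(k) > 0) reject[ord[seq_len(max(k))]] <- TRUE
  reject
}

# Type-7 (linear interpolation) percentile from first principles.
oracle_percentile <- function(x, prob) {
  s <- sort(x)
  h <- (length(s) - 1) * prob + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Pearson chi-square on a 2x2 table from the definition.
oracle_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# Build a phase matrix with frequency metadata the way segment_phases does.
make_phase_matrix <- function(mat, freqs) {
  dimnames(mat) <- list(format(freqs, trim = TRUE), NULL)
  attr(mat, "freqs") <- freqs
  mat
}

# Small montage helper for preprocessing tests.
make_rec <- function(data, rate = 100, labels = NULL, eog = "EOG") {
  if (is.null(labels))
    labels <- c(paste0("ch", seq_len(nrow(data) - 1)), eog)
  eeg_recording(data, rate = rate, labels = labels, eog_label = eog)
}
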