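test_that("segment phases recover on-bin sinusoid phases and segment counts", {
  t <- (0:999) / 100                       # 10 s at 100 Hz
  ph <- segment_phases(cos(2 * pi * 41 * t), rate = 100)
  expect_equal(ncol(ph), 5)                # 10 s / 2 s bins
  expect_equal(nrow(ph), 99)               # 0.5 .. 49.5 Hz
  expect_lt(max(abs(ph["41", ] - ph["41", 1])), 1e-9)
  expect_equal(unname(ph["41", 1]), 0, tolerance = 1e-9)
  # 5 ms delay shifts the 41 Hz phase by -2*pi*41*0.005
  ph_d <- segment_phases(cos(2 * pi * 41 * (t - 0.005)), rate = 100)
  shift <- wrap_phase(ph_d["41", 1] - ph["41", 1])
  expect_equal(unname(shift), wrap_phase(-2 * pi * 41 * 0.005),
               tolerance = 1e-9)
  expect_error(segment_phases(stats::rnorm(100), rate = 100),
               "shorter than one")
})

test_that("phase coherence matches its definition in closed-form cases", {
  # perfect locking: constant phase difference
  a <- make_phase_matrix(matrix(0.7, 1, 8), 41)
  b <- make_phase_matrix(matrix(0.4, 1, 8), 41)
  res <- phase_coherence(a, b)
  expect_equal(res$coherence_norm, 1)
  expect_equal(res$rayleigh_z, 8)
  expect_equal(res$resultant, 8)
  # symmetric cancellation
  a4 <- make_phase_matrix(matrix(c(0, pi / 2, pi, 3 * pi / 2), 1, 4), 41)
  b4 <- make_phase_matrix(matrix(0, 1, 4), 41)
  expect_equal(phase_coherence(a4, b4)$resultant, 0, tolerance = 1e-12)
  # errors
  expect_error(phase_coherence(a, make_phase_matrix(matrix(0, 1, 4), 41)),
               "same shape")
  expect_error(phase_coherence(make_phase_matrix(matrix(0, 1, 1), 41),
                               make_phase_matrix(matrix(0, 1, 1), 41)),
               "2 segments")
})

test_that("vectorized coherence equals the two-loop summation oracle", {
  withr::with_seed(21, {
    for (T_seg in c(10, 50, 100)) {
      a <- make_phase_matrix(
        matrix(stats::runif(5 * T_seg, -pi, pi), 5, T_seg),
        seq(1, 3, by = 0.5))
      b <- make_phase_matrix(
        matrix(stats::runif(5 * T_seg, -pi, pi), 5, T_seg),
        seq(1, 3, by = 0.5))
      res <- phase_coherence(a, b)
      expect_equal(res$resultant, oracle_coherence(a, b), tolerance = 1e-12)
      expect_equal(res$coherence_norm, oracle_coherence(a, b) / T_seg,
                   tolerance = 1e-12)
    }
  })
})

test_that("itpc is the constant-stimulus reduction and is rotation invariant", {
  withr::with_seed(22, {
    a <- make_phase_matrix(matrix(stats::runif(3 * 50, -pi, pi), 3, 50),
                           c(2, 41, 43))
    expect_equal(itpc(a)$resultant,
                 phase_coherence(a, a * 0)$resultant, tolerance = 1e-12)
    # constant stimulus phase leaves the resultant unchanged (rotation)
    b <- make_phase_matrix(matrix(1.1, 3, 50), c(2, 41, 43))
    expect_equal(phase_coherence(a, b)$resultant, itpc(a)$resultant,
                 tolerance = 1e-10)
    # adding a common constant to response and stimulus changes nothing
    expect_equal(phase_coherence(a + 0.8, b + 0.8)$resultant,
                 phase_coherence(a, b)$resultant, tolerance = 1e-10)
  })
})

test_that("full FFT pipeline equals a direct-DFT double loop", {
  withr::with_seed(23, {
    x <- stats::rnorm(100 * 2 * 20)           # 20 segments at 100 Hz
    ph <- segment_phases(x, rate = 100)
    for (k in c(1, 41 * 2, 99)) {            # bins 0.5, 41, 49.5 Hz
      direct <- vapply(1:20, function(s)
        oracle_dft_phase(x[((s - 1) * 200 + 1):(s * 200)], k), numeric(1))
      expect_equal(unname(ph[k, ]), direct, tolerance = 1e-10)
    }
    res <- itpc(ph)
    zero <- array(0, dim = dim(ph))
    expect_equal(res$resultant, oracle_coherence(ph, zero),
                 tolerance = 1e-10)
  })
})

test_that("chance-level coherence has the Rayleigh expectation sqrt(pi)/(2 sqrt(T))", {
  T_seg <- 1800
  vals <- withr::with_seed(24, vapply(1:200, function(i) {
    th <- stats::runif(T_seg, -pi, pi)
    sqrt(sum(cos(th))^2 + sum(sin(th))^2) / T_seg
  }, numeric(1)))
  expect_equal(mean(vals), sqrt(pi) / (2 * sqrt(T_seg)), tolerance = 0.1)
})

test_that("band features reduce the spectrum to the six ROI means", {
  freqs <- seq(0.5, 49.5, by = 0.5)
  base <- tidyr::expand_grid(channel = roi_centrofrontal(), freq_hz = freqs)
  ones <- dplyr::mutate(base, participant_id = "p1", condition = "tone",
                        n_segments = 10L, resultant = 10,
                        coherence_norm = 1, rayleigh_z = 10, mean_phase = 0)
  f1 <- band_features(ones)
  expect_equal(unlist(f1[, c("coh_41", "coh_41pm2", "coh_2", "coh_4",
                             "coh_delta", "coh_theta")], use.names = FALSE),
               rep(1, 6))
  # hand-built 3-channel spectrum against spreadsheet-style means
  withr::with_seed(25, {
    chans <- c("Fz", "Cz", "C3")
    sp <- tidyr::expand_grid(channel = chans, freq_hz = freqs) |>
      dplyr::mutate(participant_id = "p2", condition = "tone",
                    n_segments = 10L,
                    coherence_norm = stats::runif(dplyr::n()),
                    resultant = 10 * .data$coherence_norm,
                    rayleigh_z = 10 * .data$coherence_norm^2, mean_phase = 0)
    f3 <- band_features(sp, roi = chans)
    by_hand <- function(fs) mean(sp$coherence_norm[sp$freq_hz %in% fs])
    expect_equal(f3$coh_41, by_hand(41))
    expect_equal(f3$coh_41pm2, by_hand(c(39, 43)))
    expect_equal(f3$coh_delta, by_hand(seq(0.5, 3.5, 0.5)))
    expect_equal(f3$coh_theta, by_hand(seq(4, 8, 0.5)))
    # one-channel ROI gives that channel's values
    fz <- band_features(sp, roi = "Fz")
    expect_equal(fz$coh_2,
                 sp$coherence_norm[sp$channel == "Fz" & sp$freq_hz == 2])
  })
  expect_error(band_features(ones, roi = character(0)), "empty ROI")
  expect_error(band_features(ones, roi = c(roi_centrofrontal(), "Oz")),
               "absent")
  expect_error(band_features(dplyr::filter(ones, freq_hz != 39)), "missing")
})

test_that("signed topography negates channels more than 90 degrees from Fz", {
  sp <- tibble::tibble(
    participant_id = "p", condition = "tone",
    channel = c("Fz", "Cz", "C1", "C2", "C3"),
    freq_hz = 41, n_segments = 10L,
    resultant = c(8, 6, 6, 6, 0),
    coherence_norm = c(0.8, 0.6, 0.6, 0.6, 0),
    rayleigh_z = 1, mean_phase = c(0, pi, pi / 2, 0.5, 0))
  expect_warning(topo <- signed_topography(sp, 41), "zero resultant")
  v <- stats::setNames(topo$signed_coherence, topo$channel)
  expect_gt(v["Fz"], 0)                      # reference always positive
  expect_equal(unname(v["Cz"]), -0.6)        # pi away -> negated
  expect_equal(unname(v["C1"]), 0.6)         # exactly 90 deg -> kept positive
  expect_equal(unname(v["C2"]), 0.6)
  expect_error(signed_topography(sp, 10), "not present")
})

test_that("topography normalization divides by the 95th percentile", {
  sp <- tibble::tibble(
    participant_id = "p", condition = "tone",
    channel = sprintf("ch%02d", 1:20), freq_hz = 41, n_segments = 10L,
    coherence_norm = 0.1 * (1:20), resultant = 1:20,
    rayleigh_z = 1, mean_phase = 0)
  sp$channel[1] <- "Fz"
  topo <- signed_topography(sp, 41, reference = "Fz")
  norm <- normalize_topography(topo)
  q_oracle <- oracle_percentile(abs(topo$signed_coherence), 0.95)
  expect_equal(attr(norm, "normalizer"), q_oracle)
  expect_equal(norm$signed_coherence,
               topo$signed_coherence / q_oracle)
  expect_identical(sign(norm$signed_coherence), sign(topo$signed_coherence))
  # all-equal values collapse to exactly 1
  spc <- dplyr::mutate(sp, coherence_norm = 0.4)
  expect_equal(normalize_topography(
    signed_topography(spc, 41))$signed_coherence, rep(1, 20))
})
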