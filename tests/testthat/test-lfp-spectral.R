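test_that("preprocessing preserves the passband and rejects out-of-band energy", {
  fs <- 2500
  t <- (0:(10 * fs - 1)) / fs
  mid <- 5000:20000                         # away from filter edges

  rec50 <- list(lfp = matrix(sin(2 * pi * 50 * t), 1), fs = fs)
  out50 <- preprocess_lfp(rec50)
  expect_equal(out50$fs, 1250)
  expect_equal(ncol(out50$lfp), 12500)
  # 50 Hz is deep in the passband: amplitude within 1%
  expect_equal(sd(out50$lfp[1, 2500:10000]) * sqrt(2), 1, tolerance = 0.01)

  # 600 Hz sits in the stopband; compare to the designed response,
  # squared for forward-backward filtering
  rec600 <- list(lfp = matrix(sin(2 * pi * 600 * t), 1), fs = fs)
  out600_full <- signal::filtfilt(signal::butter(3, c(0.1, 400) / 1250, "pass"),
                                  rec600$lfp[1, ])
  H <- Mod(signal::freqz(signal::butter(3, c(0.1, 400) / 1250, "pass"),
                         Fs = fs, n = 4096)$h)
  H600 <- H[which.min(abs(seq(0, fs / 2, length.out = 4096) - 600))]^2
  expect_equal(sd(out600_full[mid]) * sqrt(2), H600, tolerance = 0.1 * H600)
  expect_lt(H600, 0.2)

  # DC is removed by the 0.1 Hz high-pass edge (forward-backward)
  recdc <- list(lfp = matrix(rep(2, 10 * fs), 1), fs = fs)
  expect_lt(max(abs(preprocess_lfp(recdc)$lfp)), 2)

  expect_error(preprocess_lfp(list(lfp = matrix(0, 1, 1000), fs = 3000)),
               "multiple")
})

test_that("epoching returns per-trial means and SEMs with the right shape", {
  fs <- 1000
  n <- 20 * fs
  sig <- sin(2 * pi * 7 * (0:(n - 1)) / fs)
  onsets <- c(2, 6, 10, 14)

  # identical trials: SEM is zero everywhere, mean equals the epoch
  # (onsets aligned to the 7 Hz cycle so all epochs see the same waveform)
  rec <- list(lfp = matrix(sig, 1), fs = fs)
  aligned <- round(onsets * 7) / 7
  ev <- epoch_and_average(rec, aligned, window = c(-0.5, 2))
  expect_lt(max(ev$sem), 1e-6)
  expect_equal(ev$n_trials, 4)
  expect_equal(length(ev$time_s), 2.5 * fs)
  expect_equal(range(ev$time_s), c(-0.5, 2 - 1 / fs))

  # single event: the mean is that epoch
  one <- epoch_and_average(rec, 3, window = c(-0.5, 2))
  idx <- round(3 * fs) + 1 + seq(round(-0.5 * fs), round(2 * fs) - 1)
  expect_equal(one$mean[1, ], sig[idx])

  # iid noise: SEM ~ sigma / sqrt(n_trials)
  set.seed(1)
  sigma <- 2
  recn <- list(lfp = matrix(rnorm(60 * fs, sd = sigma), 1), fs = fs)
  onsn <- seq(1, 55, by = 3)
  evn <- epoch_and_average(recn, onsn, window = c(-0.5, 2))
  expect_equal(mean(evn$sem), sigma / sqrt(length(onsn)), tolerance = 0.05)

  expect_error(epoch_and_average(rec, numeric(0)), "no events")
  expect_error(epoch_and_average(rec, 19.9, window = c(-0.5, 2)), "trial 1")
})

test_that("Welch PSD localizes a tone and flattens white noise", {
  fs <- 1250
  t <- (0:(2 * fs - 1)) / fs
  x <- sin(2 * pi * 10.29 * t)
  w <- welch_psd(x, fs, segment_s = 1, overlap_frac = 0.5)
  pk <- w$freq_hz[which.max(w$psd[1, ])]
  expect_lt(abs(pk - 10.29), fs / (1 * fs))   # within one bin

  set.seed(2)
  wn <- welch_psd(rnorm(200 * fs), fs, segment_s = 0.5, overlap_frac = 0.5)
  sel <- wn$freq_hz > 20 & wn$freq_hz < 600
  fit <- lm(log(wn$psd[1, sel]) ~ log(wn$freq_hz[sel]))
  expect_lt(abs(coef(fit)[2]), 0.1)           # spectral slope ~ 0
  # Parseval: integrated PSD ~ signal variance
  expect_equal(sum(wn$psd[1, ]) * (wn$freq_hz[2] - wn$freq_hz[1]), 1,
               tolerance = 0.05)

  z <- welch_psd(numeric(1000), fs, segment_s = 0.25)
  expect_equal(max(z$psd), 0)
  expect_error(welch_psd(x, fs, segment_s = 3), "segment")
})

test_that("the S-transform matches its direct-sum definition and localizes tones", {
  # brute-force oracle equality on seeded random signals
  set.seed(7)
  for (n in c(16, 37, 64)) {
    x <- rnorm(n)
    impl <- stockwell_transform(x, fs = n, f_lo = 0, f_hi = n / 2)
    oracle <- stockwell_direct(x, fs = n, f_lo = 0, f_hi = n / 2)
    expect_equal(impl$freq_hz, oracle$freq_hz)
    expect_lt(max(Mod(impl$S - oracle$S)) / max(Mod(oracle$S)), 1e-10)
  }

  # a unit sinusoid's time-averaged magnitude peaks at its own row
  fs <- 256
  x <- sin(2 * pi * 40 * (0:(2 * fs - 1)) / fs)
  s <- stockwell_transform(x, fs, 5, 100)
  expect_equal(s$freq_hz[which.max(rowMeans(s$magnitude))], 40,
               tolerance = 0.51)

  # a constant signal lives entirely in the f = 0 voice
  sc <- stockwell_transform(rep(3, 64), 64, 0, 32)
  expect_equal(sc$magnitude[1, ], rep(3, 64))
  expect_lt(max(sc$magnitude[-1, ]), 1e-6)

  expect_error(stockwell_transform(numeric(0), 100), "empty")
  expect_error(stockwell_transform(rnorm(10), 100, 60, 40), "f_lo")
})

test_that("the evoked-contrast spectrum is bounded and matches worked values", {
  # construct a synthetic time-frequency object directly
  t_axis <- seq(-0.5, 2, by = 0.01)
  nf <- 5
  mk_tf <- function(stim_val, base_val) {
    mag <- array(base_val, dim = c(nf, length(t_axis), 2))
    mag[, t_axis >= 0, ] <- stim_val
    structure(list(magnitude = mag, freq_hz = seq(100, 140, by = 10),
                   time_s = t_axis), class = "tf_spectrum")
  }
  # equal stimulus and baseline power: z identically 0
  expect_equal(max(abs(zscore_spectrum(mk_tf(1, 1))$z)), 0)
  # stimulus 3 vs baseline 1: z = (3 - 1)/(3 + 1) = 0.5 exactly
  expect_equal(unique(as.vector(zscore_spectrum(mk_tf(3, 1))$z)), 0.5)
  # bounds on randomized non-negative spectra
  set.seed(3)
  for (i in 1:20) {
    mag <- array(rexp(nf * length(t_axis) * 2), c(nf, length(t_axis), 2))
    z <- zscore_spectrum(structure(list(magnitude = mag,
                                        freq_hz = seq(100, 140, 10),
                                        time_s = t_axis),
                                   class = "tf_spectrum"))$z
    expect_true(all(z > -1 & z <= 1))
  }
  # zero total power yields z = 0 with a warning
  expect_warning(z0 <- zscore_spectrum(mk_tf(0, 0)), "zero total power")
  expect_equal(max(abs(z0$z)), 0)
  expect_equal(z0$n_zero_denominator, nf * 2)
})

test_that("high-frequency amplitude follows the abs-of-channel-sum rule", {
  mk_z <- function(zmat, f = seq(100, 190, by = 1)) {
    structure(list(z = zmat, freq_hz = f, n_zero_denominator = 0L),
              class = "z_spectrum")
  }
  nf <- 91
  expect_equal(hf_amplitude(mk_z(matrix(0, nf, 4))), 0)
  # constant z = c on k channels over a W Hz band: amplitude = c * k * W
  expect_equal(hf_amplitude(mk_z(matrix(0.2, nf, 6))), 0.2 * 6 * 90,
               tolerance = 1e-9)
  # channel-range restriction
  expect_equal(hf_amplitude(mk_z(matrix(0.2, nf, 6)), channel_range = c(1, 3)),
               0.2 * 3 * 90, tolerance = 1e-9)
  # equal-magnitude positive and negative channels cancel inside the abs
  zpm <- cbind(rep(0.3, nf), rep(-0.3, nf))
  expect_equal(hf_amplitude(mk_z(zpm)), 0)
  expect_error(hf_amplitude(mk_z(matrix(0, nf, 2)), channel_range = c(1, 5)),
               "channel_range")
  # a band outside the computed frequency axis is rejected
  expect_error(hf_amplitude(mk_z(matrix(0, nf, 2)), band = c(50, 190)),
               "exceeds")
})

test_that("high-frequency size counts channels above the cumulative threshold", {
  mk_z <- function(zmat, f = seq(100, 190, by = 1)) {
    structure(list(z = zmat, freq_hz = f, n_zero_denominator = 0L),
              class = "z_spectrum")
  }
  nf <- 91
  s0 <- hf_size(mk_z(matrix(0, nf, 10)))
  expect_equal(s0$size_channels, 0)
  expect_equal(s0$size_um, 0)
  expect_false(s0$large)
  # z = 0.2 over the 91-bin band on 60 of 80 channels:
  # score = 0.2 * 91 = 18.2 > 15 -> 60 channels = 600 um > 500 um
  zm <- matrix(0, nf, 80)
  zm[, 11:70] <- 0.2
  s <- hf_size(mk_z(zm), threshold = 15, pitch_um = 10)
  expect_equal(s$size_channels, 60)
  expect_equal(s$size_um, 600)
  expect_true(s$large)
  expect_equal(which(s$above), 11:70)
  expect_equal(unname(s$score[11]), 0.2 * 91, tolerance = 1e-9)
})
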