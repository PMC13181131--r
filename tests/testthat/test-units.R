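test_that("MUA extraction finds injected spikes and rejects common-mode noise", {
  fs <- 30000
  n <- 2 * fs
  set.seed(4)
  noise <- matrix(rnorm(4 * n, sd = 5), 4, n)

  # biphasic template at 6 SD of the filtered noise, injected on channel 2
  tpl_t <- seq(0, 1e-3, by = 1 / fs)
  tpl <- -exp(-(tpl_t - 3e-4)^2 / (2 * 6e-5^2)) +
    0.5 * exp(-(tpl_t - 6e-4)^2 / (2 * 1e-4^2))
  inj_times <- c(0.3, 0.7, 1.1, 1.5)
  x <- noise
  for (ti in inj_times) {
    i0 <- round(ti * fs)
    x[2, i0:(i0 + length(tpl) - 1)] <- x[2, i0:(i0 + length(tpl) - 1)] +
      6 * 5 * tpl / max(abs(tpl))
  }
  ev <- extract_mua(x, fs = fs, threshold_sd = 4)
  for (ti in inj_times)
    expect_true(any(abs(ev[[2]] - (ti + 3e-4)) < 2e-4))

  # a common-mode artifact on all channels is removed by the median
  art <- matrix(rnorm(4 * n, sd = 0.01), 4, n)
  burst <- 500 * sin(2 * pi * 1000 * (0:999) / fs)
  for (ch in 1:4) art[ch, 10000:10999] <- art[ch, 10000:10999] + burst
  ev_art <- extract_mua(art, fs = fs, threshold_sd = 4)
  # without referencing, the 33 ms burst alone would fire ~30 merged events
  in_burst <- vapply(ev_art, function(e)
    sum(e > 10000 / fs - 2e-3 & e < 11000 / fs + 2e-3), numeric(1))
  expect_true(all(in_burst <= 3))

  expect_warning(extract_mua(matrix(rnorm(n), 1, n), fs = fs),
                 "single-channel")
})

test_that("threshold-crossing rate on Gaussian noise matches the Rice rate", {
  fs <- 30000
  dur <- 40
  set.seed(6)
  x <- matrix(rnorm(2 * dur * fs), 2, dur * fs)
  ev <- extract_mua(x, fs = fs, threshold_sd = 4, dead_time_ms = 1)
  observed <- mean(lengths(ev)) / dur
  # Rice rate of the band-passed process through the designed filter,
  # doubled for both-sign crossings
  H2 <- Mod(signal::freqz(signal::butter(2, c(300, 3000) / (fs / 2), "pass"),
                          Fs = fs, n = 8192)$h)^4   # filtfilt: |H|^2 twice
  f <- seq(0, fs / 2, length.out = 8192)
  m0 <- pracma::trapz(f, H2)
  m2 <- pracma::trapz(f, f^2 * H2)
  expected <- 2 * sqrt(m2 / m0) * exp(-16 / 2)
  expect_gt(observed, expected / 2)
  expect_lt(observed, expected * 2)
})

test_that("waveforms are classified by trough-to-peak duration at 0.43 ms", {
  mk <- function(gap_samples, fs) {
    w <- numeric(200)
    w[51] <- -100
    w[51 + gap_samples] <- 40
    classify_waveform(w, fs = fs)
  }
  expect_equal(mk(9, 30000)$cls, "narrow")    # 0.30 ms
  expect_equal(mk(18, 30000)$cls, "broad")    # 0.60 ms
  # exactly 0.43 ms (43 samples at 100 kHz): boundary goes to broad
  got <- mk(43, 1e5)
  expect_equal(got$peak_to_trough_ms, 0.43)
  expect_equal(got$cls, "broad")
  expect_error(classify_waveform(seq(1, 0, length.out = 50), fs = 30000),
               "unclassifiable")
})

test_that("ISI violation fractions count refractory intervals", {
  expect_equal(isi_violation_fraction(seq(0, 10, by = 0.1))$fraction, 0)
  # regular train plus one extra spike 0.5 ms after the last: 997 ISIs
  spikes <- c(seq(0, 49.8, by = 0.05), 49.8 + 5e-4)
  got <- isi_violation_fraction(sort(spikes), refractory_ms = 2)
  expect_equal(got$fraction, 1 / 997)
  expect_false(got$pass_qc)                      # 1/997 > 0.05%
  # Poisson train: P(ISI < d) = 1 - exp(-rate * d)
  set.seed(10)
  pois <- cumsum(rexp(20000, rate = 50))
  expect_equal(isi_violation_fraction(pois, 2)$fraction,
               1 - exp(-50 * 0.002), tolerance = 0.05)
  deg <- isi_violation_fraction(c(1))
  expect_true(deg$degenerate)
  expect_equal(deg$fraction, 0)
})

test_that("responsiveness gate compares evoked peak to baseline mean + 7.5 SD", {
  mk_psth <- function(base, evoked) {
    structure(list(rate = c(base, rep(0, 20), evoked),
                   t_s = c(seq(-0.475, -0.025, length.out = length(base)),
                           seq(0, 0.475, length.out = 20),
                           seq(0.5, 2, length.out = length(evoked))),
                   bin_ms = 25, n_trials = 10), class = "psth")
  }
  base <- rep(c(1, 3), 10)                       # mean 2, SD ~ 1.026
  expect_false(is_responsive(mk_psth(rep(2, 20), rep(2, 20))))
  expect_true(is_responsive(mk_psth(base, c(rep(2, 19), 12))))
  expect_false(is_responsive(mk_psth(base, c(rep(2, 19), 9))))
  # degenerate all-zero baseline: responsive iff any evoked spike
  expect_true(is_responsive(mk_psth(rep(0, 20), c(rep(0, 19), 1))))
  expect_false(is_responsive(mk_psth(rep(0, 20), rep(0, 20))))
})

test_that("PSTH estimates trial-aligned rates", {
  onsets <- c(10, 20, 30)
  spikes <- as.vector(outer(c(0.11, 0.13, 0.15, 1.01), onsets, "+"))
  p <- psth(spikes, onsets, window = c(-0.5, 2), bin_ms = 100)
  expect_equal(sum(p$rate) * 0.1 * 3, length(spikes))
  expect_equal(p$rate[p$t_s > 0.1 & p$t_s < 0.2], 30)  # 3 spikes/trial/0.1s
})

test_that("STA receptive fields recover ground-truth centers", {
  cfg <- synthetic_config(rng_seed = 12, n_units = 2)
  centers <- rbind(c(30, 0), c(-120, 45))
  sn <- generate_sparse_noise_responses(cfg, centers_deg = centers,
                                        n_frames = 3000)
  rf1 <- sta_receptive_field(sn$spikes[[1]], sn)
  rf2 <- sta_receptive_field(sn$spikes[[2]], sn)
  # centers within one 15-degree grid square
  expect_lt(max(abs(rf1$center_deg - centers[1, ])), 15)
  expect_lt(max(abs(rf2$center_deg - centers[2, ])), 15)
  expect_gt(rf1$snr, 15)
  expect_gt(rf1$size_deg, 0)
  # an untuned unit: uniform spikes, flat STA below the SNR gate
  set.seed(13)
  flat <- sort(runif(2000, 0, max(sn$frames$onset_s)))
  rf_flat <- sta_receptive_field(flat, sn)
  expect_lt(rf_flat$snr, 15)
  # pairwise center distance approximates the generated separation
  d_true <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  d_est <- sqrt(sum((rf1$center_deg - rf2$center_deg)^2))
  expect_lt(abs(d_est - d_true), 15)
  expect_error(sta_receptive_field(numeric(0), sn), "no spikes")
})

test_that("retinotopic coverage is the maximal pairwise center distance", {
  mk_rf <- function(az, el, snr = 20)
    structure(list(center_deg = c(azimuth_deg = az, elevation_deg = el),
                   snr = snr), class = "receptive_field")
  expect_equal(retinotopic_coverage(list(mk_rf(5, 5), mk_rf(5, 5)))$coverage_deg, 0)
  expect_equal(
    retinotopic_coverage(list(mk_rf(0, 0), mk_rf(30, 40)))$coverage_deg, 50)
  # gated fields only; fewer than 2 gated -> undefined
  out <- retinotopic_coverage(list(mk_rf(0, 0), mk_rf(30, 40, snr = 3)))
  expect_false(out$defined)
  expect_true(is.na(out$coverage_deg))
  # a tangential-style layout spanning > 100 degrees
  wide <- list(mk_rf(-60, 0), mk_rf(0, 10), mk_rf(55, -5))
  expect_gt(retinotopic_coverage(wide)$coverage_deg, 100)
})

test_that("spike phases are cycle fractions of the repeat-frequency sinusoid", {
  expect_equal(spike_phases(5, 10, 5)$phases, 0)
  expect_equal(spike_phases(5.15, 10, 5)$phases, 0.5)   # 1.5 cycles
  train <- 5 + (0:19) / 10
  ph_tr <- spike_phases(train, 10, 5)$phases
  expect_true(all(pmin(ph_tr, 1 - ph_tr) < 1e-9))   # circular distance to 0
  # spikes outside the stimulus window are excluded
  ph <- spike_phases(c(4.9, 5.1, 7.5), 10, 5, trial_duration_s = 2)
  expect_equal(ph$n_spikes, 1)
  expect_error(spike_phases(1, -1, 0), "positive")
})

test_that("PPC matches its pairwise definition and is rotation invariant", {
  expect_equal(ppc(rep(0.3, 50))$ppc, 1, tolerance = 1e-12)
  expect_equal(ppc(c(0.1, 0.6))$ppc, -1, tolerance = 1e-12)
  expect_false(ppc(c(0.2))$defined)

  set.seed(14)
  for (n in c(2, 7, 50, 200)) {
    ph <- runif(n)
    expect_equal(ppc(ph)$ppc, ppc_bruteforce(ph), tolerance = 1e-10)
    # global phase rotation leaves PPC unchanged
    expect_equal(ppc((ph + 0.37) %% 1)$ppc, ppc(ph)$ppc, tolerance = 1e-10)
  }

  # uniform phases: unbiased around zero
  set.seed(15)
  reps <- replicate(20, ppc(runif(10000))$ppc)
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps)), 3 * se + 1e-6)
})

test_that("phase locking falls with repeat frequency at fixed millisecond jitter", {
  # lattice spiking with fixed 4 ms Gaussian jitter: higher repeat
  # frequencies smear more of the cycle, so PPC must decrease
  set.seed(16)
  jitter_sd <- 0.004
  mean_ppc <- vapply(c(10.3, 24, 40), function(f) {
    mean(replicate(10, {
      t0 <- seq(0, 2, by = 1 / f)
      spikes <- t0 + rnorm(length(t0), sd = jitter_sd)
      ppc(spike_phases(spikes, f, 0, trial_duration_s = Inf))$ppc
    }))
  }, numeric(1))
  expect_true(all(diff(mean_ppc) < 0))
})

test_that("per-unit PPC aggregates by recording then mouse", {
  df <- data.frame(mouse = c(1, 1, 1, 2), recording = c("a", "a", "b", "c"),
                   unit_id = 1:4, ppc = c(0.2, 0.4, 0.6, 0.1))
  agg <- aggregate_ppc(df)
  expect_equal(agg$ppc[agg$mouse == 1], mean(c(mean(c(0.2, 0.4)), 0.6)))
  expect_equal(agg$ppc[agg$mouse == 2], 0.1)
})
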