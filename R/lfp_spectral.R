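#' Band-pass filter and downsample an LFP recording
#'
#' Zero-phase (forward-backward) Butterworth order-3 band-pass between
#' `band[1]` and `band[2]` Hz, followed by downsampling to `fs_out` by
#' averaging blocks of neighboring samples (pairs for 2500 -> 1250 Hz).
#' Channel count is preserved.
#'
#' @param rec list with `lfp` (channels x samples matrix, uV) and `fs`;
#'   e.g. a [generate_lfp()] or [read_recording()] result.
#' @param band band-pass corner frequencies, Hz.
#' @param fs_out output sampling rate; `rec$fs` must be an integer
#'   multiple of it.
#' @return `rec` with filtered, downsampled `lfp` and updated `fs`.
#' @export
preprocess_lfp <- function(rec, band = c(0.1, 400), fs_out = 1250) {
  fs <- rec$fs
  factor <- fs / fs_out
  if (abs(factor - round(factor)) > 1e-9)
    fail("fs (", fs, ") must be an integer multiple of fs_out (", fs_out, ")")
  factor <- as.integer(round(factor))
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  x <- rec$lfp
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n_keep <- (ncol(x) %/% factor) * factor
  out <- matrix(0, nrow = nrow(x), ncol = n_keep %/% factor)
  for (ch in seq_len(nrow(x))) {
    y <- signal::filtfilt(bf, x[ch, ])
    out[ch, ] <- colMeans(matrix(y[seq_len(n_keep)], nrow = factor))
  }
  rec$lfp <- out
  rec$fs <- fs_out
  rec
}

#' Epoch around trial onsets and average across trials
#'
#' Cuts a fixed window around each event onset and returns the per-channel
#' trial mean and SEM: the evoked LFP.
#'
#' @param rec list with `lfp` (channels x samples) and `fs`.
#' @param events numeric vector of onset times (s), or a data.frame with an
#'   `onset_s` column.
#' @param window two-element window relative to onset, seconds
#'   (default `c(-0.5, 2)`).
#' @return an object of class `evoked_lfp`: `mean` and `sem`
#'   (channels x time), `time_s`, `n_trials`, `label`.
#' @export
epoch_and_average <- function(rec, events, window = c(-0.5, 2)) {
  onsets <- if (is.data.frame(events)) events$onset_s else events
  label <- if (is.data.frame(events) && !is.null(events$label))
    events$label[1] else NA_character_
  if (length(onsets) == 0) fail("no events to epoch around")
  fs <- rec$fs
  x <- rec$lfp
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  i_rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1L)
  nt <- length(i_rel)
  nch <- nrow(x)
  acc <- matrix(0, nch, nt)
  acc2 <- matrix(0, nch, nt)
  for (k in seq_along(onsets)) {
    idx <- round(onsets[k] * fs) + 1L + i_rel
    if (idx[1] < 1 || idx[nt] > ncol(x))
      fail("trial ", k, " window [", window[1], ", ", window[2],
           "] s falls outside the recording")
    ep <- x[, idx, drop = FALSE]
    acc <- acc + ep
    acc2 <- acc2 + ep^2
  }
  n <- length(onsets)
  m <- acc / n
  sem <- if (n > 1) sqrt(pmax(acc2 / n - m^2, 0) * n / (n - 1)) / sqrt(n)
  else matrix(NA_real_, nch, nt)
  structure(list(mean = m, sem = sem, time_s = i_rel / fs, fs = fs,
                 n_trials = n, label = label),
            class = "evoked_lfp")
}

#' Welch power spectral density
#'
#' Segment-averaged periodogram with a Hann window: the signal is split
#' into overlapping segments, each windowed and Fourier transformed, and
#' the one-sided power densities averaged.
#'
#' @param x numeric vector, or channels x samples matrix, or an
#'   `evoked_lfp` (its trial mean is used).
#' @param fs sampling rate, Hz (taken from `x` if it is an `evoked_lfp`).
#' @param segment_s segment length, seconds.
#' @param overlap_frac fractional overlap between consecutive segments.
#' @return list with `freq_hz` and `psd` (channels x frequency, uV^2/Hz).
#' @export
welch_psd <- function(x, fs = NULL, segment_s = 1, overlap_frac = 0.5) {
  if (inherits(x, "evoked_lfp")) { fs <- x$fs; x <- x$mean }
  if (is.null(fs)) fail("fs is required")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  nseg <- round(segment_s * fs)
  if (nseg < 8 || nseg > ncol(x))
    fail("segment length (", nseg, " samples) must be in [8, n_samples]")
  if (overlap_frac < 0 || overlap_frac >= 1)
    fail("overlap_frac must be in [0, 1)")
  step <- max(1L, round(nseg * (1 - overlap_frac)))
  starts <- seq(1L, ncol(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))
  u <- sum(w^2)
  kmax <- nseg %/% 2
  psd <- matrix(0, nrow(x), kmax + 1)
  for (ch in seq_len(nrow(x))) {
    acc <- numeric(kmax + 1)
    for (s in starts) {
      seg <- x[ch, s:(s + nseg - 1)] * w
      p <- Mod(stats::fft(seg))^2 / (fs * u)
      half <- p[1:(kmax + 1)]
      half[2:(kmax + 1)] <- 2 * half[2:(kmax + 1)]
      if (nseg %% 2 == 0) half[kmax + 1] <- half[kmax + 1] / 2
      acc <- acc + half
    }
    psd[ch, ] <- acc / length(starts)
  }
  list(freq_hz = (0:kmax) * fs / nseg, psd = psd)
}

#' Discrete Stockwell (S-) transform of one channel
#'
#' Time-frequency decomposition with a frequency-scaled Gaussian window: a
#' phase-corrected continuous wavelet transform generalizing the short-time
#' Fourier transform. Computed in the frequency domain: the signal's DFT is
#' shifted by each voice frequency, multiplied by the sampled Gaussian
#' window `exp(-2*pi^2*m^2/k^2)`, and inverse transformed, one voice per
#' DFT frequency row in `[f_lo, f_hi]`. The `f = 0` voice, if requested, is
#' the signal mean.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi frequency band limits, Hz (`0 <= f_lo < f_hi <= fs/2`).
#' @return list with `magnitude` (frequency x time), `S` (complex,
#'   frequency x time), `freq_hz`, `time_s`.
#' @export
stockwell_transform <- function(x, fs, f_lo = 0, f_hi = fs / 2) {
  n <- length(x)
  if (n == 0) fail("empty signal")
  if (f_lo < 0 || f_hi <= f_lo || f_hi > fs / 2)
    fail("need 0 <= f_lo < f_hi <= fs/2")
  X <- stats::fft(x) / n
  df <- fs / n
  k_all <- 0:(n %/% 2)
  keep <- k_all * df >= f_lo - 1e-12 & k_all * df <= f_hi + 1e-12
  rows <- k_all[keep]
  m <- 0:(n - 1)
  m_wrapped <- ifelse(m > n / 2, m - n, m)   # symmetric frequency offsets
  S <- matrix(0 + 0i, length(rows), n)
  for (i in seq_along(rows)) {
    k <- rows[i]
    if (k == 0) {
      S[i, ] <- mean(x) + 0i
    } else {
      Xs <- X[(m + k) %% n + 1]
      G <- exp(-2 * pi^2 * m_wrapped^2 / k^2)
      S[i, ] <- stats::fft(Xs * G, inverse = TRUE)
    }
  }
  list(magnitude = Mod(S), S = S, freq_hz = rows * df,
       time_s = (0:(n - 1)) / fs)
}

#' Time-frequency spectrum of an evoked LFP, all channels
#'
#' Applies [stockwell_transform()] to each channel of the trial-averaged
#' evoked LFP, keeping magnitudes only.
#'
#' @param evoked an [epoch_and_average()] result.
#' @param f_lo,f_hi analysis band, Hz.
#' @return object of class `tf_spectrum`: `magnitude` (frequency x time x
#'   channel array), `freq_hz`, `time_s` (relative to stimulus onset).
#' @export
evoked_tf_spectrum <- function(evoked, f_lo, f_hi) {
  nch <- nrow(evoked$mean)
  first <- stockwell_transform(evoked$mean[1, ], evoked$fs, f_lo, f_hi)
  mag <- array(0, dim = c(length(first$freq_hz), length(first$time_s), nch))
  mag[, , 1] <- first$magnitude
  if (nch > 1) for (ch in 2:nch)
    mag[, , ch] <- stockwell_transform(evoked$mean[ch, ], evoked$fs,
                                       f_lo, f_hi)$magnitude
  structure(list(magnitude = mag, freq_hz = first$freq_hz,
                 time_s = evoked$time_s), class = "tf_spectrum")
}

#' Normalized evoked-contrast spectrum (stimulus vs baseline)
#'
#' For every (frequency, channel): `A` = time-mean of the S-transform
#' magnitude over the stimulus window, `B` = time-mean over the pre-stimulus
#' baseline; the evoked contrast is `z = (A - B) / (A + B)`, bounded in
#' (-1, 1) for non-negative spectra, 0 when stimulus and baseline power are
#' equal. Bins with `A + B = 0` get `z = 0` and are counted in
#' `n_zero_denominator`.
#'
#' @param tf a [evoked_tf_spectrum()] result (time axis relative to onset).
#' @param stim_window stimulus window, s (default `c(0, 2)`).
#' @param baseline_window baseline window, s (default `c(-0.5, -0.005)`).
#' @return object of class `z_spectrum`: `z` (frequency x channel),
#'   `freq_hz`, `n_zero_denominator`.
#' @export
zscore_spectrum <- function(tf, stim_window = c(0, 2),
                            baseline_window = c(-0.5, -0.005)) {
  t <- tf$time_s
  i_stim <- t >= stim_window[1] & t <= stim_window[2]
  i_base <- t >= baseline_window[1] & t <= baseline_window[2]
  if (!any(i_stim) || !any(i_base))
    fail("time axis does not cover the stimulus and baseline windows")
  mag <- tf$magnitude
  if (length(dim(mag)) == 2) mag <- array(mag, dim = c(dim(mag), 1))
  nf <- dim(mag)[1]; nch <- dim(mag)[3]
  A <- apply(mag[, i_stim, , drop = FALSE], c(1, 3), mean)
  B <- apply(mag[, i_base, , drop = FALSE], c(1, 3), mean)
  den <- A + B
  z <- matrix(0, nf, nch)
  ok <- den > 0
  z[ok] <- (A[ok] - B[ok]) / den[ok]
  n_zero <- sum(!ok)
  if (n_zero > 0)
    warning(n_zero, " (frequency, channel) bins had zero total power; ",
            "their z was set to 0")
  structure(list(z = z, freq_hz = tf$freq_hz, n_zero_denominator = n_zero),
            class = "z_spectrum")
}

# interpolate a z-spectrum onto the fixed 1 Hz analysis grid over `band`
z_on_grid <- function(z, band, grid_step = 1) {
  if (band[1] < min(z$freq_hz) - 1e-9 || band[2] > max(z$freq_hz) + 1e-9)
    fail("band [", band[1], ", ", band[2],
         "] Hz exceeds the z-spectrum frequency axis")
  fgrid <- seq(band[1], band[2], by = grid_step)
  zg <- apply(z$z, 2, function(col)
    stats::approx(z$freq_hz, col, xout = fgrid, rule = 2)$y)
  if (is.null(dim(zg))) zg <- matrix(zg, nrow = length(fgrid))
  list(freq_hz = fgrid, z = zg)
}

#' Amplitude of high-frequency enhancement
#'
#' Sums the evoked-contrast spectrum over a channel range, takes absolute
#' values, and integrates (trapezoid) the resulting frequency profile over
#' the high-frequency band on a fixed 1 Hz grid:
#' `Amp = AUC_f(|sum_ch z(f, ch)|)`.
#'
#' @param z a [zscore_spectrum()] result.
#' @param channel_range two-element channel range (1-based, inclusive);
#'   `NULL` for all channels.
#' @param band frequency band, Hz (default `c(100, 190)`).
#' @return amplitude in a.u.
#' @export
hf_amplitude <- function(z, channel_range = NULL, band = c(100, 190)) {
  nch <- ncol(z$z)
  chans <- if (is.null(channel_range)) seq_len(nch)
  else {
    if (channel_range[1] < 1 || channel_range[2] > nch ||
        channel_range[2] < channel_range[1])
      fail("channel_range must lie within 1..", nch)
    channel_range[1]:channel_range[2]
  }
  g <- z_on_grid(z, band)
  profile <- abs(rowSums(g$z[, chans, drop = FALSE]))
  pracma::trapz(g$freq_hz, profile)
}

#' Spatial size of high-frequency enhancement
#'
#' Per channel, sums the evoked contrast over the high-frequency band on
#' the fixed 1 Hz grid and takes the absolute value; channels whose
#' cumulative score exceeds `threshold` (15 a.u. by default) count toward
#' the spatial extent, converted to micrometers via the channel pitch.
#' Extents above 500 um flag a spatially large enhancement.
#'
#' @param z a [zscore_spectrum()] result.
#' @param threshold cumulative-score threshold, a.u.
#' @param band frequency band, Hz.
#' @param pitch_um distance between neighboring channels, um.
#' @param channel_range optional channel range to evaluate (others are
#'   reported but never counted).
#' @return list: `size_channels`, `size_um`, `large` (size_um > 500),
#'   `score` (per-channel cumulative |sum|), `above` (logical).
#' @export
hf_size <- function(z, threshold = 15, band = c(100, 190), pitch_um = 10,
                    channel_range = NULL) {
  g <- z_on_grid(z, band)
  score <- abs(colSums(g$z))
  above <- score > threshold
  if (!is.null(channel_range)) {
    sel <- seq_along(score) >= channel_range[1] &
      seq_along(score) <= channel_range[2]
    above <- above & sel
  }
  n <- sum(above)
  list(size_channels = n, size_um = n * pitch_um,
       large = n * pitch_um > 500, score = score, above = above)
}

#' Full LFP high-frequency analysis for one recording
#'
#' Convenience chain: [preprocess_lfp()] -> [epoch_and_average()] ->
#' [evoked_tf_spectrum()] -> [zscore_spectrum()] -> [hf_amplitude()] and
#' [hf_size()].
#'
#' @param rec recording list (`lfp`, `fs`, `events`, optionally
#'   `channel_pitch_um`).
#' @param band high-frequency band, Hz.
#' @param threshold size threshold, a.u.
#' @param channel_range channel range for the amplitude sum; `NULL` = all.
#' @param f_margin extra Hz analyzed on each side of `band`.
#' @return list with `z`, `amplitude_auc`, `size` and the analysis
#'   parameters.
#' @export
analyze_lfp_hf <- function(rec, band = c(100, 190), threshold = 15,
                           channel_range = NULL, f_margin = 10) {
  pre <- preprocess_lfp(rec)
  evoked <- epoch_and_average(pre, rec$events)
  tf <- evoked_tf_spectrum(evoked, max(0, band[1] - f_margin),
                           min(pre$fs / 2, band[2] + f_margin))
  z <- zscore_spectrum(tf)
  pitch <- if (!is.null(rec$channel_pitch_um)) rec$channel_pitch_um else 10
  list(z = z,
       amplitude_auc = hf_amplitude(z, channel_range, band),
       size = hf_size(z, threshold, band, pitch, channel_range),
       band = band, threshold = threshold, channel_range = channel_range)
}
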