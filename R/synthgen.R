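#' Configuration for the synthetic Neuropixels-like recording generator
#'
#' Holds the recording geometry and all ground-truth parameters: 1/f
#' background noise, stimulus-locked SSVEP entrainment, an injectable
#' narrow-band high-frequency (HF) power increase over a contiguous channel
#' span, and spike-train phase locking.
#'
#' @param n_channels number of LFP channels (probe default 384).
#' @param fs_lfp LFP sampling rate, Hz (default 2500).
#' @param fs_ap action-potential band sampling rate, Hz (default 30000;
#'   used only for short AP-band segments).
#' @param channel_pitch_um distance between neighboring sorted channels, um.
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background.
#' @param background_rms_uV RMS of the background noise per channel, uV.
#' @param ssvep_amplitude amplitude of the stimulus-locked fundamental, uV.
#' @param ssvep_harmonics number of harmonics (amplitude falls off as 1/h).
#' @param hf_band two-element numeric, the high-frequency band in Hz.
#' @param hf_span_channels two-element integer, first and last channel
#'   (1-based, inclusive) receiving injected HF power; `NULL` for none.
#' @param hf_gain multiplicative increase of hf-band power during
#'   stimulation on the span channels (1 = no injection).
#' @param n_units number of synthetic units.
#' @param baseline_rate_hz mean spike rate per unit, Hz.
#' @param locking_kappa von Mises concentration of spike phases relative to
#'   the stimulus repeat frequency (0 = no locking; `Inf` = delta at the
#'   preferred phase).
#' @param preferred_phase preferred phase in cycles, in `[0, 1)`.
#' @param modulation_depth fraction of the rate that is phase-modulated
#'   (1 = fully locked mixture, 0 = homogeneous regardless of kappa).
#' @param rng_seed integer seed; identical seeds give bit-identical output.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 384, fs_lfp = 2500, fs_ap = 30000,
                             channel_pitch_um = 10, noise_exponent = 1,
                             background_rms_uV = 30, ssvep_amplitude = 20,
                             ssvep_harmonics = 3, hf_band = c(100, 190),
                             hf_span_channels = NULL, hf_gain = 1,
                             n_units = 20, baseline_rate_hz = 5,
                             locking_kappa = 0, preferred_phase = 0.25,
                             modulation_depth = 1, rng_seed = 1L) {
  if (length(hf_band) != 2 || hf_band[1] <= 0 || hf_band[2] <= hf_band[1])
    fail("hf_band must be an increasing positive pair")
  if (hf_band[2] >= fs_lfp / 2)
    fail("hf_band top (", hf_band[2], " Hz) must be below the LFP Nyquist (",
         fs_lfp / 2, " Hz)")
  if (!is.null(hf_span_channels)) {
    if (length(hf_span_channels) != 2 ||
        hf_span_channels[1] < 1 || hf_span_channels[2] > n_channels ||
        hf_span_channels[2] < hf_span_channels[1])
      fail("hf_span_channels must lie within 1..n_channels")
  }
  if (hf_gain < 0 || baseline_rate_hz < 0 || ssvep_amplitude < 0 ||
      background_rms_uV < 0)
    fail("rates, gains and amplitudes must be non-negative")
  if (locking_kappa < 0) fail("locking_kappa must be >= 0")
  if (modulation_depth < 0 || modulation_depth > 1)
    fail("modulation_depth must be in [0, 1]")
  structure(as.list(environment()), class = "synthetic_config")
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Hermitian-symmetric frequency-domain synthesis of coloured Gaussian noise.
# amp_fun(f_Hz) gives the one-sided amplitude profile; returns a real series
# of length n with deterministic per-bin magnitudes (random phases only), so
# band powers are analytically known.
colored_noise <- function(n, fs, amp_fun) {
  kmax <- floor(n / 2)
  f <- (1:kmax) * fs / n
  amp <- amp_fun(f)
  phases <- stats::runif(kmax, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  full <- complex(real = numeric(n))
  full[2:(kmax + 1)] <- spec
  # mirror the negative frequencies; Nyquist bin (even n) must be real
  if (n %% 2 == 0) {
    full[kmax + 1] <- complex(real = amp[kmax] * sign(cos(phases[kmax])))
    if (kmax > 1) full[n:(n - kmax + 2)] <- Conj(spec[1:(kmax - 1)])
  } else {
    full[n:(n - kmax + 1)] <- Conj(spec)
  }
  Re(stats::fft(full, inverse = TRUE)) / n
}

# variance of colored_noise output contributed by bins inside [f1, f2]
colored_noise_band_var <- function(n, fs, amp_fun, f1, f2) {
  kmax <- floor(n / 2)
  f <- (1:kmax) * fs / n
  amp <- amp_fun(f)
  sel <- f >= f1 & f <= f2
  2 * sum(amp[sel]^2) / n^2
}

# sample-index mask of stimulus windows for a schedule, at rate fs
stim_window_mask <- function(schedule, fs, n_samples) {
  mask <- logical(n_samples)
  dur <- schedule$spec$trial_duration_s
  for (on in schedule$events$onset_s) {
    i0 <- floor(on * fs) + 1L
    i1 <- min(n_samples, floor((on + dur) * fs))
    if (i0 <= i1) mask[i0:i1] <- TRUE
  }
  mask
}

#' Generate the LFP part of a synthetic recording
#'
#' Per channel: 1/f^alpha Gaussian background, plus (during stimulus
#' windows) a stimulus-locked harmonic series at the schedule's repeat
#' frequency with a per-channel phase offset mimicking retinotopic
#' progression, plus (on the configured channel span, stimulus windows
#' only) band-limited Gaussian noise scaled so that hf-band power is
#' `hf_gain` times the background's band power. Deterministic given
#' `rng_seed`.
#'
#' @param config a [synthetic_config()].
#' @param schedule a [build_sequential_schedule()] result.
#' @return an object of class `synthetic_recording` with elements `lfp`
#'   (channels x samples matrix, uV), `fs`, `channel_pitch_um`, `events`
#'   (trial onset data.frame), `spec`, and `truth` (injected span, gain,
#'   SSVEP parameters).
#' @export
generate_lfp <- function(config, schedule) {
  fs <- config$fs_lfp
  n_samples <- ceiling(schedule$duration_s * fs)
  nch <- config$n_channels
  alpha <- config$noise_exponent
  amp_fun <- function(f) 1 / pmax(f, 1)^(alpha / 2)
  # normalize so background RMS hits the configured value
  base_var <- colored_noise_band_var(n_samples, fs, amp_fun, 0, fs / 2)
  scale <- config$background_rms_uV / sqrt(base_var)
  band_var <- scale^2 *
    colored_noise_band_var(n_samples, fs, amp_fun,
                           config$hf_band[1], config$hf_band[2])
  f_rep <- repeat_frequency(schedule$spec)
  mask <- stim_window_mask(schedule, fs, n_samples)
  span <- config$hf_span_channels
  inject_sd <- if (!is.null(span) && config$hf_gain != 1)
    sqrt(abs(config$hf_gain - 1) * band_var) * sign(config$hf_gain - 1)
  else 0
  hf_amp_fun <- function(f)
    ifelse(f >= config$hf_band[1] & f <= config$hf_band[2], 1, 0)
  hf_var <- colored_noise_band_var(n_samples, fs, hf_amp_fun,
                                   config$hf_band[1], config$hf_band[2])

  # SSVEP template, one trial, re-used for every trial (coherent across
  # trials, as for a stimulus-locked response)
  trial_n <- floor(schedule$spec$trial_duration_s * fs)
  tt <- (seq_len(trial_n) - 1) / fs
  harmonics <- seq_len(max(config$ssvep_harmonics, 0))

  lfp <- matrix(0, nrow = nch, ncol = n_samples)
  # background stream is independent of the injection stream, so changing
  # hf_gain leaves the background realization untouched
  with_seed(config$rng_seed, {
    for (ch in seq_len(nch)) {
      x <- scale * colored_noise(n_samples, fs, amp_fun)
      if (config$ssvep_amplitude > 0 && length(harmonics) > 0) {
        phi <- 2 * pi * (ch - 1) / nch   # retinotopic phase progression
        ss <- numeric(trial_n)
        for (h in harmonics)
          ss <- ss + (config$ssvep_amplitude / h) *
            sin(2 * pi * f_rep * h * tt + h * phi)
        for (on in schedule$events$onset_s) {
          i0 <- floor(on * fs) + 1L
          i1 <- min(n_samples, i0 + trial_n - 1L)
          x[i0:i1] <- x[i0:i1] + ss[seq_len(i1 - i0 + 1L)]
        }
      }
      lfp[ch, ] <- x
    }
  })
  if (!identical(inject_sd, 0) && !is.null(span)) {
    with_seed(config$rng_seed + 101L, {
      for (ch in span[1]:span[2]) {
        y <- colored_noise(n_samples, fs, hf_amp_fun) / sqrt(hf_var)
        lfp[ch, mask] <- lfp[ch, mask] + inject_sd * y[mask]
      }
    })
  }
  structure(list(lfp = lfp, fs = fs,
                 channel_pitch_um = config$channel_pitch_um,
                 events = schedule$events, spec = schedule$spec,
                 truth = list(hf_span = span, hf_gain = config$hf_gain,
                              hf_band = config$hf_band, f_rep = f_rep,
                              ssvep_amplitude = config$ssvep_amplitude)),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat("<synthetic_recording>", nrow(x$lfp), "ch x", ncol(x$lfp),
      "samples @", x$fs, "Hz;", nrow(x$events), "trials of",
      x$spec$kind, "\n")
  invisible(x)
}

#' Generate phase-locked synthetic spike trains
#'
#' Each unit is an inhomogeneous Poisson process whose rate during stimulus
#' windows is modulated by a von Mises profile over the phase of a fixed
#' sinusoid at the stimulus repeat frequency, anchored at each trial onset:
#' `rate(t) = r * ((1 - m) + m * exp(kappa * cos(2*pi*(phase - mu))) / I0(kappa))`.
#' Spike phases are therefore von Mises(2*pi*mu, kappa) distributed when
#' `m = 1`; `kappa = 0` gives a homogeneous Poisson process. During the
#' inter-trial gray the rate is the unmodulated baseline. `kappa = Inf`
#' places one spike exactly at the preferred phase of every cycle.
#' Deterministic given `rng_seed`.
#'
#' @param config a [synthetic_config()].
#' @param schedule a [build_sequential_schedule()] result.
#' @return list with `spikes` (list of ascending spike-time vectors, s) and
#'   `units` (data.frame: unit_id, kappa, preferred_phase, rate_hz).
#' @export
generate_spikes <- function(config, schedule) {
  if (config$baseline_rate_hz < 0) fail("baseline rate must be non-negative")
  f_rep <- repeat_frequency(schedule$spec)
  r <- config$baseline_rate_hz
  kappa <- config$locking_kappa
  m <- config$modulation_depth
  mu <- config$preferred_phase
  dur <- schedule$spec$trial_duration_s
  onsets <- schedule$events$onset_s
  spikes <- vector("list", config$n_units)
  with_seed(config$rng_seed + 1L, {
    for (u in seq_len(config$n_units)) {
      if (is.infinite(kappa)) {
        st <- unlist(lapply(onsets, function(on) {
          k <- 0:(floor(dur * f_rep) - 1)
          on + (k + mu) / f_rep
        }))
      } else {
        lmax <- r * ((1 - m) + m * exp(kappa) / besselI(kappa, 0))
        st <- unlist(lapply(onsets, function(on) {
          n_cand <- stats::rpois(1, lmax * dur)
          tc <- sort(stats::runif(n_cand, 0, dur))
          ph <- (tc * f_rep) %% 1
          lam <- r * ((1 - m) + m * exp(kappa * cos(2 * pi * (ph - mu))) /
                        besselI(kappa, 0))
          on + tc[stats::runif(n_cand) < lam / lmax]
        }))
        # homogeneous firing in the gray intervals
        gaps <- rbind(c(0, onsets[1]),
                      cbind(onsets + dur,
                            c(onsets[-1], schedule$duration_s)))
        iti <- unlist(apply(gaps, 1, function(g) {
          if (g[2] <= g[1]) return(numeric(0))
          n <- stats::rpois(1, r * (g[2] - g[1]))
          stats::runif(n, g[1], g[2])
        }))
        st <- sort(c(st, iti))
      }
      spikes[[u]] <- st
    }
  })
  list(spikes = spikes,
       units = data.frame(unit_id = seq_len(config$n_units), kappa = kappa,
                          preferred_phase = mu, rate_hz = r))
}

#' Generate unit waveform templates in two duration classes
#'
#' Emits biphasic templates (negative trough followed by a positive peak)
#' whose trough-to-peak durations are drawn from disjoint ranges on either
#' side of the 0.43 ms broad/narrow boundary: narrow in
#' `[0.20, 0.41]` ms, broad in `[0.45, 0.80]` ms, snapped to the AP-band
#' sample grid. Each template carries its ground-truth class label.
#'
#' @param config a [synthetic_config()].
#' @param n_narrow,n_broad number of templates per class.
#' @return list of `unit_waveform` objects (see [classify_waveform()]),
#'   each with a `true_class` element.
#' @export
generate_waveforms <- function(config, n_narrow = 5, n_broad = 5) {
  fs <- config$fs_ap
  dt_ms <- 1000 / fs
  n <- round(2.5e-3 * fs)            # 2.5 ms template
  t_ms <- (seq_len(n) - 1) * dt_ms
  trough_ms <- 0.8
  make <- function(dur_ms, cls) {
    dur_ms <- round(dur_ms / dt_ms) * dt_ms   # snap to sample grid
    peak_ms <- trough_ms + dur_ms
    w <- -100 * exp(-(t_ms - trough_ms)^2 / (2 * 0.08^2)) +
      45 * exp(-(t_ms - peak_ms)^2 / (2 * (0.10 + 0.25 * dur_ms)^2))
    structure(list(template = w, fs = fs, true_class = cls),
              class = "unit_waveform")
  }
  with_seed(config$rng_seed + 2L, {
    narrow <- lapply(stats::runif(n_narrow, 0.20, 0.41), make, cls = "narrow")
    broad <- lapply(stats::runif(n_broad, 0.45, 0.80), make, cls = "broad")
  })
  c(narrow, broad)
}

#' Sparse-noise stimulus frames and spatially tuned spike responses
#'
#' Builds a pseudo-random sparse-noise sequence (two targets per 100 ms
#' frame on a 36 x 22 grid of 15 degree squares) and draws Poisson spikes
#' for units with Gaussian spatial tuning around known receptive-field
#' centers, giving ground truth for STA recovery tests.
#'
#' @param config a [synthetic_config()].
#' @param centers_deg matrix/data.frame of unit RF centers, columns
#'   `(azimuth_deg, elevation_deg)`; `NULL` draws `config$n_units` random
#'   centers well inside the grid.
#' @param n_frames number of 100 ms frames.
#' @param tuning_sigma_deg Gaussian tuning width, degrees.
#' @param peak_rate_hz evoked rate at the RF center, Hz.
#' @param base_rate_hz untuned background rate, Hz.
#' @return list with `frames` (data.frame: frame, onset_s, target1, target2
#'   as linear grid indices), `grid` (geometry), `spikes` (per unit),
#'   `centers_deg` (ground truth).
#' @export
generate_sparse_noise_responses <- function(config, centers_deg = NULL,
                                            n_frames = 4000,
                                            tuning_sigma_deg = 12,
                                            peak_rate_hz = 60,
                                            base_rate_hz = 0.5) {
  grid <- sparse_noise_grid()
  frame_s <- 0.1
  with_seed(config$rng_seed + 3L, {
    ncell <- grid$n_az * grid$n_el
    frames <- data.frame(
      frame = seq_len(n_frames),
      onset_s = (seq_len(n_frames) - 1) * frame_s,
      target1 = sample.int(ncell, n_frames, replace = TRUE),
      target2 = sample.int(ncell, n_frames, replace = TRUE))
    if (is.null(centers_deg)) {
      centers_deg <- cbind(
        azimuth_deg = stats::runif(config$n_units,
                                   grid$az_deg[5], grid$az_deg[grid$n_az - 4]),
        elevation_deg = stats::runif(config$n_units,
                                     grid$el_deg[4], grid$el_deg[grid$n_el - 3]))
    }
    centers_deg <- as.matrix(centers_deg)
    az_of <- grid$az_deg[(frames$target1 - 1) %% grid$n_az + 1]
    el_of <- grid$el_deg[(frames$target1 - 1) %/% grid$n_az + 1]
    az2 <- grid$az_deg[(frames$target2 - 1) %% grid$n_az + 1]
    el2 <- grid$el_deg[(frames$target2 - 1) %/% grid$n_az + 1]
    spikes <- vector("list", nrow(centers_deg))
    for (u in seq_len(nrow(centers_deg))) {
      d1 <- (az_of - centers_deg[u, 1])^2 + (el_of - centers_deg[u, 2])^2
      d2 <- (az2 - centers_deg[u, 1])^2 + (el2 - centers_deg[u, 2])^2
      rate <- base_rate_hz + peak_rate_hz *
        (exp(-d1 / (2 * tuning_sigma_deg^2)) +
           exp(-d2 / (2 * tuning_sigma_deg^2)))
      counts <- stats::rpois(n_frames, rate * frame_s)
      st <- rep(frames$onset_s, counts) +
        stats::runif(sum(counts), 0, frame_s)
      spikes[[u]] <- sort(st)
    }
  })
  list(frames = frames, grid = grid, spikes = spikes,
       centers_deg = centers_deg)
}

#' Sparse-noise grid geometry
#'
#' The 36 x 22 grid of 15 degree squares used for receptive-field mapping,
#' with degree coordinates of the square centers (grid centered on 0).
#'
#' @return list with `n_az`, `n_el`, `square_deg`, `az_deg`, `el_deg`.
#' @export
sparse_noise_grid <- function() {
  n_az <- 36L; n_el <- 22L; sq <- 15
  list(n_az = n_az, n_el = n_el, square_deg = sq,
       az_deg = (seq_len(n_az) - (n_az + 1) / 2) * sq,
       el_deg = (seq_len(n_el) - (n_el + 1) / 2) * sq)
}

#' Write a recording as flat binary + JSON sidecar
#'
#' Little-endian int16, channels interleaved per sample, with a JSON
#' sidecar carrying `n_channels`, `fs`, `gain_uV_per_bit` and `pitch_um`.
#' Events go to `events.csv` and the ground truth to `truth.json`.
#'
#' @param rec a [generate_lfp()] result.
#' @param dir output directory (created if needed).
#' @param gain_uV_per_bit quantization step; default scales the data to
#'   about 90% of the int16 range.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir, gain_uV_per_bit = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(gain_uV_per_bit))
    gain_uV_per_bit <- max(abs(rec$lfp)) / (0.9 * 32767)
  q <- as.integer(round(rec$lfp / gain_uV_per_bit))   # column-major ==
  con <- file(file.path(dir, "lfp.bin"), "wb")        # channel-interleaved
  writeBin(q, con, size = 2L, endian = "little")
  close(con)
  jsonlite::write_json(
    list(n_channels = nrow(rec$lfp), fs = rec$fs,
         gain_uV_per_bit = gain_uV_per_bit,
         pitch_um = rec$channel_pitch_um),
    file.path(dir, "lfp.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(rec$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rec$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a flat-binary recording written by [write_recording()]
#'
#' @param dir directory with `lfp.bin`, `lfp.json`, `events.csv` (and
#'   optionally `truth.json`).
#' @return a `synthetic_recording`-shaped list (`lfp` in uV).
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "lfp.json"),
                              simplifyVector = TRUE)
  sz <- file.info(file.path(dir, "lfp.bin"))$size
  n_samples <- sz / (2 * meta$n_channels)
  if (n_samples != round(n_samples))
    fail("lfp.bin size is not a multiple of n_channels * 2 bytes")
  con <- file(file.path(dir, "lfp.bin"), "rb")
  q <- readBin(con, "integer", n = meta$n_channels * n_samples, size = 2L,
               signed = TRUE, endian = "little")
  close(con)
  lfp <- matrix(q * meta$gain_uV_per_bit, nrow = meta$n_channels)
  truth <- if (file.exists(file.path(dir, "truth.json")))
    jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  structure(list(lfp = lfp, fs = meta$fs,
                 channel_pitch_um = meta$pitch_um,
                 events = utils::read.csv(file.path(dir, "events.csv")),
                 truth = truth),
            class = "synthetic_recording")
}

#' Write spike trains to CSV
#' @param spk a [generate_spikes()] result (or list of spike-time vectors).
#' @param path output CSV (`unit_id,time_s`).
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(spk, path) {
  trains <- if (is.list(spk) && !is.null(spk$spikes)) spk$spikes else spk
  df <- data.frame(
    unit_id = rep(seq_along(trains), lengths(trains)),
    time_s = unlist(trains))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from a `unit_id,time_s` CSV
#' @param path CSV path.
#' @return list of ascending spike-time vectors indexed by unit id.
#' @export
read_spikes_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df$time_s, factor(df$unit_id, levels = sort(unique(df$unit_id)))),
         sort)
}
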