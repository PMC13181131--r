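#' Extract multi-unit activity from an AP-band segment
#'
#' Common-median reference (median across channels, per sample) is
#' subtracted, the signal band-passed 0.3-3 kHz (Butterworth order 2,
#' zero-phase), and events kept wherever the magnitude exceeds
#' `threshold_sd` standard deviations of the channel; events closer than
#' `dead_time_ms` on one channel are merged.
#'
#' @param ap list with `data` (channels x samples, uV) and `fs` (30 kHz
#'   default), or a bare matrix with `fs` supplied.
#' @param fs sampling rate if `ap` is a matrix.
#' @param threshold_sd detection threshold in channel SD units.
#' @param band band-pass corners, Hz.
#' @param dead_time_ms merge window, ms.
#' @return list of per-channel event-time vectors (seconds).
#' @export
extract_mua <- function(ap, fs = 30000, threshold_sd = 4,
                        band = c(300, 3000), dead_time_ms = 1) {
  if (is.list(ap) && !is.null(ap$data)) { fs <- ap$fs; ap <- ap$data }
  if (is.null(dim(ap))) ap <- matrix(ap, nrow = 1)
  if (nrow(ap) == 1) {
    warning("single-channel segment: common-median subtraction skipped")
    ref <- ap
  } else {
    ref <- sweep(ap, 2, apply(ap, 2, stats::median))
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  dead <- round(dead_time_ms * fs / 1000)
  out <- vector("list", nrow(ref))
  for (ch in seq_len(nrow(ref))) {
    y <- signal::filtfilt(bf, ref[ch, ])
    thr <- threshold_sd * stats::sd(y)
    idx <- which(abs(y) > thr)
    if (length(idx) > 1)
      idx <- idx[c(TRUE, diff(idx) > dead)]
    out[[ch]] <- (idx - 1) / fs
  }
  out
}

#' Classify a unit waveform as broad or narrow
#'
#' Measures the trough-to-peak duration (time from the template minimum to
#' the subsequent maximum) and splits at 0.43 ms: strictly shorter is
#' narrow (putative fast-spiking inhibitory), otherwise broad (putative
#' regular-spiking excitatory). The boundary itself is assigned to broad.
#'
#' @param w a `unit_waveform` (list with `template` and `fs`), or a bare
#'   numeric template with `fs` supplied.
#' @param fs sampling rate if `w` is a vector.
#' @param boundary_ms class boundary, ms.
#' @return list with `cls` (`"broad"`/`"narrow"`) and `peak_to_trough_ms`.
#' @export
classify_waveform <- function(w, fs = 30000, boundary_ms = 0.43) {
  if (is.list(w)) { fs <- w$fs; w <- w$template }
  i_trough <- which.min(w)
  if (i_trough >= length(w))
    fail("template has no samples after its trough; unclassifiable")
  after <- w[(i_trough + 1):length(w)]
  i_peak <- i_trough + which.max(after)
  if (w[i_peak] <= w[i_trough] || all(diff(w) >= 0) || all(diff(w) <= 0))
    fail("template is monotone; unclassifiable")
  dur_ms <- (i_peak - i_trough) * 1000 / fs
  list(cls = if (dur_ms < boundary_ms) "narrow" else "broad",
       peak_to_trough_ms = dur_ms)
}

#' Fraction of inter-spike intervals violating the refractory period
#'
#' Units pass quality control when the fraction is below 0.05%.
#'
#' @param spikes ascending spike times, s.
#' @param refractory_ms refractory period, ms.
#' @return list with `fraction`, `n_isi`, `pass_qc` (fraction < 5e-4),
#'   `degenerate` (TRUE when fewer than 2 spikes).
#' @export
isi_violation_fraction <- function(spikes, refractory_ms = 2) {
  if (length(spikes) < 2)
    return(list(fraction = 0, n_isi = 0L, pass_qc = TRUE, degenerate = TRUE))
  if (is.unsorted(spikes)) fail("spike times must be ascending")
  isi <- diff(spikes)
  frac <- mean(isi < refractory_ms / 1000)
  list(fraction = frac, n_isi = length(isi), pass_qc = frac < 5e-4,
       degenerate = FALSE)
}

#' Peri-stimulus time histogram
#'
#' Trial-aligned spike rate in fixed bins over a window around stimulus
#' onset.
#'
#' @param spikes spike times, s.
#' @param onsets trial onset times, s.
#' @param window window relative to onset, s.
#' @param bin_ms bin width, ms.
#' @return object of class `psth`: `rate` (spikes/s per bin), `t_s` (bin
#'   centers), `bin_ms`, `n_trials`.
#' @export
psth <- function(spikes, onsets, window = c(-0.5, 2), bin_ms = 25) {
  bw <- bin_ms / 1000
  edges <- seq(window[1], window[2], by = bw)
  counts <- numeric(length(edges) - 1)
  for (on in onsets) {
    rel <- spikes[spikes >= on + window[1] & spikes < on + window[2]] - on
    counts <- counts + graphics::hist(rel, breaks = edges, plot = FALSE)$counts
  }
  structure(list(rate = counts / (length(onsets) * bw),
                 t_s = edges[-1] - bw / 2, bin_ms = bin_ms,
                 n_trials = length(onsets)), class = "psth")
}

#' Responsiveness gate on a PSTH
#'
#' A unit is visually responsive when its peak evoked rate (500 ms to 2 s
#' after onset) reaches the baseline mean plus `snr_factor` times the
#' baseline SD, both computed over the pre-stimulus bins (-500 to -5 ms).
#' A zero-variance baseline degenerates to "peak evoked rate exceeds the
#' baseline mean" (for a silent baseline: any evoked spike).
#'
#' @param p a [psth()] result.
#' @param snr_factor threshold multiplier (default 7.5).
#' @param baseline_window,evoked_window analysis windows, s.
#' @return logical.
#' @export
is_responsive <- function(p, snr_factor = 7.5,
                          baseline_window = c(-0.5, -0.005),
                          evoked_window = c(0.5, 2)) {
  ib <- p$t_s >= baseline_window[1] & p$t_s <= baseline_window[2]
  ie <- p$t_s >= evoked_window[1] & p$t_s <= evoked_window[2]
  if (!any(ib) || !any(ie)) fail("PSTH does not cover both windows")
  b <- p$rate[ib]
  # zero-variance baseline: the SNR gate degenerates to "exceeds baseline"
  if (stats::sd(b) == 0) return(max(p$rate[ie]) > mean(b))
  max(p$rate[ie]) >= mean(b) + snr_factor * stats::sd(b)
}

# separable natural-cubic-spline upsampling of a 2-D map
interp2_cubic <- function(map, factor = 4) {
  n1 <- nrow(map); n2 <- ncol(map)
  x1 <- seq_len(n1); x2 <- seq_len(n2)
  x1o <- seq(1, n1, length.out = (n1 - 1) * factor + 1)
  x2o <- seq(1, n2, length.out = (n2 - 1) * factor + 1)
  tmp <- apply(map, 2, function(col)
    stats::spline(x1, col, xout = x1o, method = "natural")$y)
  up <- t(apply(tmp, 1, function(row)
    stats::spline(x2, row, xout = x2o, method = "natural")$y))
  list(map = up, x1 = x1o, x2 = x2o)
}

#' Spike-triggered-average receptive field from sparse noise
#'
#' Averages the sparse-noise target maps over the frames containing each
#' spike, upsamples the STA by 2-D cubic interpolation, and reports the
#' receptive-field center (interpolated peak, degrees), size (width of the
#' half-peak region along azimuth and elevation through the peak) and an
#' SNR (peak deviation from the map mean over the SD of the outermost
#' one-square ring).
#'
#' @param spikes spike times, s.
#' @param sparse sparse-noise stimulus as returned in
#'   [generate_sparse_noise_responses()]: list with `frames` (frame,
#'   onset_s, target1, target2) and `grid`.
#' @param upsample interpolation factor.
#' @return object of class `receptive_field`: `map` (n_el x n_az STA),
#'   `center_deg` (azimuth, elevation), `size_deg` (mean half-peak width),
#'   `snr`, `n_spikes`.
#' @export
sta_receptive_field <- function(spikes, sparse, upsample = 4) {
  if (length(spikes) == 0) fail("no spikes; cannot estimate an STA")
  grid <- sparse$grid
  frames <- sparse$frames
  frame_s <- diff(frames$onset_s[1:2])
  fi <- floor((spikes - frames$onset_s[1]) / frame_s) + 1L
  fi <- fi[fi >= 1 & fi <= nrow(frames)]
  if (length(fi) == 0) fail("no spikes fall within the sparse-noise frames")
  counts <- tabulate(fi, nbins = nrow(frames))
  acc <- numeric(grid$n_az * grid$n_el)
  nz <- which(counts > 0)
  for (f in nz) {
    acc[frames$target1[f]] <- acc[frames$target1[f]] + counts[f]
    acc[frames$target2[f]] <- acc[frames$target2[f]] + counts[f]
  }
  sta <- matrix(acc / sum(counts), nrow = grid$n_el, byrow = TRUE)
  up <- interp2_cubic(sta, upsample)
  pk <- which(up$map == max(up$map), arr.ind = TRUE)[1, ]
  el_axis <- grid$el_deg[1] + (up$x1 - 1) * grid$square_deg
  az_axis <- grid$az_deg[1] + (up$x2 - 1) * grid$square_deg
  center <- c(azimuth_deg = az_axis[pk[2]], elevation_deg = el_axis[pk[1]])
  # half-peak widths along the two axes through the peak
  half <- min(up$map) + (max(up$map) - min(up$map)) / 2
  wslice <- function(v, axis) {
    above <- v >= half
    if (!any(above)) return(0)
    diff(range(axis[above]))
  }
  size_az <- wslice(up$map[pk[1], ], az_axis)
  size_el <- wslice(up$map[, pk[2]], el_axis)
  # periphery = outermost one-square ring of the raw grid
  ring <- matrix(FALSE, grid$n_el, grid$n_az)
  ring[c(1, grid$n_el), ] <- TRUE
  ring[, c(1, grid$n_az)] <- TRUE
  periph_sd <- stats::sd(sta[ring])
  snr <- if (periph_sd > 0) max(abs(sta - mean(sta))) / periph_sd else Inf
  structure(list(map = sta, center_deg = center,
                 size_deg = mean(c(size_az, size_el)),
                 size_az_deg = size_az, size_el_deg = size_el,
                 snr = snr, n_spikes = sum(counts)),
            class = "receptive_field")
}

#' Retinotopic coverage of a set of receptive fields
#'
#' Maximal pairwise Euclidean distance between receptive-field centers (in
#' degrees) over the fields passing the SNR gate.
#'
#' @param rfs list of [sta_receptive_field()] results.
#' @param snr_gate minimal SNR for inclusion (15 a.u.).
#' @return list with `coverage_deg` (NA when fewer than 2 gated fields,
#'   with `defined = FALSE`), `n_gated`.
#' @export
retinotopic_coverage <- function(rfs, snr_gate = 15) {
  gated <- Filter(function(r) r$snr >= snr_gate, rfs)
  if (length(gated) < 2)
    return(list(coverage_deg = NA_real_, n_gated = length(gated),
                defined = FALSE))
  centers <- t(vapply(gated, function(r) r$center_deg, numeric(2)))
  list(coverage_deg = max(stats::dist(centers)), n_gated = length(gated),
       defined = TRUE)
}

#' Spike phases relative to the stimulus repeat-frequency sinusoid
#'
#' For every spike inside a stimulus window, the phase of a fixed sinusoid
#' at `f_rep` anchored at that trial's onset: `frac((t - t0) * f_rep)`, a
#' unit-less quantity in cycles `[0, 1)`.
#'
#' @param spikes spike times, s.
#' @param f_rep stimulus repeat frequency, Hz.
#' @param onsets trial onset times, s (scalar `t0` also accepted).
#' @param trial_duration_s stimulus window length per trial; `Inf` keeps
#'   every spike after the (single) anchor.
#' @return object of class `spike_phase_set`: `phases` (cycles in [0, 1)),
#'   `f_rep`, `n_spikes`.
#' @export
spike_phases <- function(spikes, f_rep, onsets, trial_duration_s = Inf) {
  if (f_rep <= 0) fail("f_rep must be positive")
  ph <- numeric(0)
  for (on in onsets) {
    inwin <- spikes >= on & spikes < on + trial_duration_s
    ph <- c(ph, ((spikes[inwin] - on) * f_rep) %% 1)
  }
  structure(list(phases = ph, f_rep = f_rep, n_spikes = length(ph)),
            class = "spike_phase_set")
}

#' Pairwise phase consistency
#'
#' The mean over all spike pairs of the cosine of their phase difference,
#' `2/(N(N-1)) * sum_{j<k} cos(theta_j)cos(theta_k) + sin(theta_j)sin(theta_k)`,
#' an unbiased, spike-count-free estimator of phase locking in `[-1, 1]`.
#' Phases in cycles are converted to radians before the trigonometry.
#' Evaluated through the resultant-length identity
#' `ppc = (|sum_j e^{i theta_j}|^2 - N) / (N(N-1))`.
#'
#' @param phases a [spike_phases()] result, or numeric phases in cycles.
#' @return list with `ppc` (NA with `defined = FALSE` for fewer than 2
#'   spikes), `n_spikes`.
#' @export
ppc <- function(phases) {
  ph <- if (inherits(phases, "spike_phase_set")) phases$phases else phases
  n <- length(ph)
  if (n < 2) return(list(ppc = NA_real_, n_spikes = n, defined = FALSE))
  theta <- 2 * pi * ph
  r2 <- Mod(sum(complex(argument = theta)))^2
  list(ppc = (r2 - n) / (n * (n - 1)), n_spikes = n, defined = TRUE)
}

#' Aggregate per-unit PPC within recordings and mice
#'
#' Units' PPC values are averaged within each recording, then recordings
#' within each mouse: mice are the unit of inference.
#'
#' @param df data.frame with columns `mouse`, `recording`, `unit_id`,
#'   `ppc`.
#' @return data.frame with one mean PPC per mouse.
#' @export
aggregate_ppc <- function(df) {
  rec <- stats::aggregate(ppc ~ mouse + recording, df, mean)
  stats::aggregate(ppc ~ mouse, rec, mean)
}
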