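#' Stimulus kinds
#'
#' Sequential kinds divide the screen into sections exposed one per frame;
#' standard kinds are the full-field / classical comparison stimuli.
#'
#' @name stimulus-kinds
#' @keywords internal
NULL

SEQUENTIAL_KINDS <- c("wedge_top", "wedge_bottom", "horizontal_bars",
                      "vertical_bars")
STANDARD_KINDS   <- c("checker", "chirp", "moving_bar", "sparse_noise", "gray")

#' Parametric stimulus description
#'
#' Describes one visual stimulus: its kind, the number of screen sections
#' (for sequential kinds), the screen refresh rate, and the trial structure
#' (2 s stimulus alternated with 2 s gray, 50 trials by default).
#'
#' Sequential stimuli split the screen into `n_sections` alternating
#' black/white checkerboard sections; exactly one section is shown per screen
#' refresh cycle, so the full set of sections repeats at
#' `refresh_hz / n_sections` Hz (the "repeat frequency").
#'
#' @param kind one of `"wedge_top"`, `"wedge_bottom"`, `"horizontal_bars"`,
#'   `"vertical_bars"` (sequential) or `"checker"`, `"chirp"`,
#'   `"moving_bar"`, `"sparse_noise"`, `"gray"` (standard).
#' @param n_sections number of screen sections (6, 7 or 14 for the
#'   sequential kinds used experimentally; any positive integer accepted).
#' @param refresh_hz screen refresh rate in Hz (144/180/240 sequential,
#'   120 standard).
#' @param trial_duration_s stimulus duration per trial, seconds.
#' @param n_trials number of trials.
#' @param iti_duration_s gray inter-trial interval, seconds.
#' @param extra named list of kind-specific parameters (e.g. moving-bar
#'   direction, checker square size, sparse-noise grid geometry).
#' @return an object of class `stimulus_spec`.
#' @examples
#' sp <- stimulus_spec("vertical_bars", n_sections = 14, refresh_hz = 144)
#' repeat_frequency(sp)
#' @export
stimulus_spec <- function(kind, n_sections = NA_integer_, refresh_hz,
                          trial_duration_s = 2, n_trials = 50,
                          iti_duration_s = 2, extra = list()) {
  kind <- match.arg(kind, c(SEQUENTIAL_KINDS, STANDARD_KINDS))
  check_positive(refresh_hz, "refresh_hz")
  check_positive(trial_duration_s, "trial_duration_s")
  if (n_trials < 1) fail("n_trials must be >= 1")
  if (iti_duration_s < 0) fail("iti_duration_s must be >= 0")
  if (kind %in% SEQUENTIAL_KINDS) {
    if (is.na(n_sections) || n_sections < 1 || n_sections != round(n_sections))
      fail("sequential stimulus '", kind, "' needs a positive integer n_sections")
    n_sections <- as.integer(n_sections)
  }
  structure(list(kind = kind, n_sections = n_sections,
                 refresh_hz = refresh_hz,
                 trial_duration_s = trial_duration_s,
                 n_trials = as.integer(n_trials),
                 iti_duration_s = iti_duration_s, extra = extra),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("<stimulus_spec>", x$kind, "\n")
  if (is_sequential(x))
    cat("  sections:", x$n_sections, " refresh:", x$refresh_hz, "Hz",
        " repeat:", round_half_up(repeat_frequency(x), 1), "Hz\n")
  else
    cat("  refresh:", x$refresh_hz, "Hz\n")
  cat("  trials:", x$n_trials, "x", x$trial_duration_s, "s (+",
      x$iti_duration_s, "s gray)\n")
  invisible(x)
}

#' Is a stimulus a sequential kind?
#' @param spec a [stimulus_spec()].
#' @return logical.
#' @export
is_sequential <- function(spec) spec$kind %in% SEQUENTIAL_KINDS

#' Per-section repeat frequency of a sequential stimulus
#'
#' One section is exposed per screen refresh cycle, so a given section is
#' re-exposed every `n_sections` frames: the repeat frequency is
#' `refresh_hz / n_sections`. The exact rational value is returned; use
#' [round_half_up()] with one decimal for reporting (e.g. 144/14 -> 10.3 Hz).
#'
#' @param spec a sequential [stimulus_spec()].
#' @return frequency in Hz (exact, unrounded).
#' @export
repeat_frequency <- function(spec) {
  if (!is_sequential(spec))
    fail("repeat_frequency is defined for sequential stimuli, not '",
         spec$kind, "'")
  if (spec$n_sections == 0) fail("n_sections must be positive")
  spec$refresh_hz / spec$n_sections
}

#' Phase shift between neighboring sections
#'
#' Neighboring sections are exposed on consecutive frames, so the phase
#' shift equals one frame period, `1000 / refresh_hz` ms (6.94 ms at 144 Hz).
#'
#' @param spec a sequential [stimulus_spec()].
#' @return phase shift in milliseconds (exact).
#' @export
section_phase_shift <- function(spec) {
  if (!is_sequential(spec))
    fail("section_phase_shift is defined for sequential stimuli, not '",
         spec$kind, "'")
  check_positive(spec$refresh_hz, "refresh_hz")
  1000 / spec$refresh_hz
}

#' Visual angle subtended by an on-screen extent
#'
#' Standard perimetric formula `2 * atan(extent / (2 * distance))`. At the
#' experimental viewing distance of 15 cm, 2.6 cm on the screen subtends
#' 10 degrees.
#'
#' @param extent_cm on-screen extent in cm.
#' @param distance_cm eye-to-screen distance in cm.
#' @return visual angle in degrees.
#' @export
visual_angle_deg <- function(extent_cm, distance_cm) {
  if (any(extent_cm < 0)) fail("extent_cm must be non-negative")
  check_positive(distance_cm, "distance_cm")
  2 * atan(extent_cm / (2 * distance_cm)) * 180 / pi
}

#' Frame-accurate schedule for a sequential stimulus
#'
#' Expands a sequential [stimulus_spec()] into its per-frame timeline:
#' `n_trials` trials of `trial_duration_s`, separated (and preceded) by gray
#' inter-trial intervals. Within a trial, frame `i` (0-based) exposes section
#' `i %% n_sections`; each trial restarts at section 0, so trials are
#' identical. Gray frames carry section index -1. Sections alternate
#' black/white checkerboard polarity, section 0 starting black.
#'
#' @param spec a sequential [stimulus_spec()].
#' @return an object of class `frame_schedule`: a list with
#'   \describe{
#'     \item{frames}{data.frame with `frame_index`, `onset_s`,
#'       `section_index` (-1 for gray), `trial_index` (NA for gray),
#'       `polarity` (+1 black-leading / -1 white-leading, NA for gray)}
#'     \item{events}{data.frame of trial onsets: `trial`, `onset_s`, `label`}
#'     \item{spec}{the input spec}
#'     \item{frame_duration_ms}{1000 / refresh_hz}
#'     \item{duration_s}{total schedule duration}
#'   }
#' @export
build_sequential_schedule <- function(spec) {
  if (!is_sequential(spec))
    fail("build_sequential_schedule requires a sequential stimulus, got '",
         spec$kind, "'")
  dt <- 1 / spec$refresh_hz
  frames_per_trial <- floor(spec$trial_duration_s * spec$refresh_hz)
  frames_per_iti <- floor(spec$iti_duration_s * spec$refresh_hz)
  n <- spec$n_trials
  sec_trial <- (seq_len(frames_per_trial) - 1L) %% spec$n_sections
  blocks <- vector("list", 2L * n)
  onsets <- numeric(n)
  t_cursor <- 0
  k <- 0L
  for (tr in seq_len(n)) {
    if (frames_per_iti > 0) {
      k <- k + 1L
      blocks[[k]] <- data.frame(
        onset_s = t_cursor + (seq_len(frames_per_iti) - 1) * dt,
        section_index = -1L, trial_index = NA_integer_)
      t_cursor <- t_cursor + frames_per_iti * dt
    }
    onsets[tr] <- t_cursor
    k <- k + 1L
    blocks[[k]] <- data.frame(
      onset_s = t_cursor + (seq_len(frames_per_trial) - 1) * dt,
      section_index = sec_trial, trial_index = tr)
    t_cursor <- t_cursor + frames_per_trial * dt
  }
  frames <- do.call(rbind, blocks[seq_len(k)])
  frames$frame_index <- seq_len(nrow(frames)) - 1L
  frames$polarity <- ifelse(frames$section_index < 0, NA_integer_,
                            1L - 2L * (frames$section_index %% 2L))
  frames <- frames[, c("frame_index", "onset_s", "section_index",
                       "trial_index", "polarity")]
  structure(list(frames = frames,
                 events = data.frame(trial = seq_len(n), onset_s = onsets,
                                     label = spec$kind),
                 spec = spec,
                 frame_duration_ms = 1000 / spec$refresh_hz,
                 duration_s = t_cursor + spec$iti_duration_s),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat("<frame_schedule>", x$spec$kind, "-", nrow(x$frames), "frames,",
      nrow(x$events), "trials,", round(x$duration_s, 2), "s\n")
  invisible(x)
}

#' Full-field chirp stimulus intensity trace
#'
#' Luminance steps followed by frequency and contrast sweeps, sampled at the
#' screen refresh rate. Segments: 2.2 s black, 3.3 s white, 3.3 s black,
#' 2.2 s gray, 8.75 s sinusoidal frequency sweep 0.5 -> 11 Hz at full
#' contrast, 8.75 s contrast sweep 0 -> 100% at 0.4 Hz, 2.2 s gray.
#' Intensity is in `[0, 1]` with gray = 0.5.
#'
#' @param refresh_hz sample (screen refresh) rate in Hz.
#' @return data.frame with `time_s` and `intensity`; attribute `segments`
#'   names each segment and its duration.
#' @export
build_chirp_trace <- function(refresh_hz = 120) {
  check_positive(refresh_hz, "refresh_hz")
  segs <- c(black1 = 2.2, white = 3.3, black2 = 3.3, gray1 = 2.2,
            freq_sweep = 8.75, contrast_sweep = 8.75, gray2 = 2.2)
  dt <- 1 / refresh_hz
  total <- sum(segs)
  t <- seq(0, total - dt / 2, by = dt)
  bounds <- cumsum(c(0, segs))
  seg_of <- findInterval(t, bounds, rightmost.closed = TRUE)
  intensity <- numeric(length(t))
  for (i in seq_along(segs)) {
    idx <- seg_of == i
    tl <- t[idx] - bounds[i]         # time within segment
    intensity[idx] <- switch(names(segs)[i],
      black1 = , black2 = 0,
      white = 1,
      gray1 = , gray2 = 0.5,
      freq_sweep = {                  # linear chirp 0.5 -> 11 Hz
        f0 <- 0.5; f1 <- 11; T <- segs[i]
        0.5 + 0.5 * sin(2 * pi * (f0 * tl + (f1 - f0) * tl^2 / (2 * T)))
      },
      contrast_sweep = {              # 0.4 Hz, contrast ramps 0 -> 100%
        0.5 + 0.5 * (tl / segs[i]) * sin(2 * pi * 0.4 * tl)
      })
  }
  out <- data.frame(time_s = t, intensity = intensity)
  attr(out, "segments") <- segs
  out
}

#' The full experimental stimulus set
#'
#' The 12 sequential stimuli (4 kinds x 3 screen refresh rates: wedges with
#' 6 sections, horizontal bars with 7, vertical bars with 14, each at
#' 144/180/240 Hz) plus the standard comparison stimuli (checker, chirp,
#' the 12 moving-bar directions, sparse noise) at 120 Hz.
#'
#' Over the 12 sequential stimuli there are 9 distinct repeat frequencies
#' (both wedge kinds share one per refresh rate), from 144/14 ~ 10.29 Hz
#' up to 240/6 = 40 Hz.
#'
#' @param include_standard include the standard comparison stimuli.
#' @return list of [stimulus_spec()] objects; sequential specs first.
#' @export
enumerate_stimulus_set <- function(include_standard = TRUE) {
  seq_kinds <- c(wedge_top = 6L, wedge_bottom = 6L,
                 horizontal_bars = 7L, vertical_bars = 14L)
  specs <- list()
  for (k in names(seq_kinds))
    for (hz in c(144, 180, 240))
      specs[[length(specs) + 1L]] <-
        stimulus_spec(k, n_sections = seq_kinds[[k]], refresh_hz = hz)
  if (include_standard) {
    specs[[length(specs) + 1L]] <- stimulus_spec(
      "checker", refresh_hz = 120,
      extra = list(square_size_deg = 10))
    specs[[length(specs) + 1L]] <- stimulus_spec(
      "chirp", refresh_hz = 120, trial_duration_s = 30.7, n_trials = 1)
    for (d in seq(0, 330, by = 30))
      specs[[length(specs) + 1L]] <- stimulus_spec(
        "moving_bar", refresh_hz = 120,
        extra = list(direction_deg = d, speed_deg_s = 90, width_deg = 10))
    specs[[length(specs) + 1L]] <- stimulus_spec(
      "sparse_noise", refresh_hz = 120, trial_duration_s = 0.1,
      n_trials = 36 * 22 * 20, iti_duration_s = 0,
      extra = list(grid = c(36L, 22L), square_deg = 15,
                   targets_per_frame = 2L, repeats_per_position = 20L))
  }
  specs
}

#' Export a frame schedule to CSV
#'
#' Writes `frame_index, onset_s, section_index, trial_index` (section -1 and
#' empty trial for gray frames), the interchange format consumed by the
#' analysis stages.
#'
#' @param schedule a [build_sequential_schedule()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(
    schedule$frames[, c("frame_index", "onset_s", "section_index",
                        "trial_index")],
    path, row.names = FALSE)
  invisible(path)
}

#' Export a stimulus spec to JSON
#' @param spec a [stimulus_spec()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_spec_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
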