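#' Configuration of a full synthetic pipeline run
#'
#' Bundles the stimulus set, generator settings, analysis parameters and
#' seed for [run_pipeline()]. The default demo covers all 12 sequential
#' stimuli (4 kinds x 144/180/240 Hz) at desk scale: one synthetic mouse,
#' 16 channels, 6 trials per condition.
#'
#' @param stimuli list of sequential [stimulus_spec()]s; default all 12.
#' @param n_mice number of synthetic mice (independent seeds).
#' @param n_channels,n_trials generator size per condition.
#' @param hf_span_channels,hf_gain injected high-frequency ground truth.
#' @param locking_kappa spike phase-locking concentration.
#' @param n_units units per condition.
#' @param band,threshold,channel_range analysis parameters (Hz, a.u.,
#'   channels).
#' @param seed integer master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(stimuli = NULL, n_mice = 1, n_channels = 16,
                       n_trials = 6, hf_span_channels = c(5, 12),
                       hf_gain = 4, locking_kappa = 1, n_units = 8,
                       band = c(100, 190), threshold = 15,
                       channel_range = NULL, seed = 1L) {
  if (is.null(stimuli))
    stimuli <- Filter(is_sequential, enumerate_stimulus_set())
  if (!all(vapply(stimuli, is_sequential, logical(1))))
    fail("run_pipeline analyzes sequential stimuli; drop standard kinds ",
         "from `stimuli`")
  structure(list(stimuli = stimuli, n_mice = as.integer(n_mice),
                 n_channels = n_channels, n_trials = n_trials,
                 hf_span_channels = hf_span_channels, hf_gain = hf_gain,
                 locking_kappa = locking_kappa, n_units = n_units,
                 band = band, threshold = threshold,
                 channel_range = channel_range, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the simulate -> analyze-lfp -> analyze-units -> compare pipeline
#'
#' For every (mouse, stimulus) cell: generates a synthetic recording,
#' quantifies the high-frequency evoked-contrast amplitude and spatial
#' size, and estimates spike phase locking (PPC) at the stimulus repeat
#' frequency. When at least five mice and two conditions are simulated, a
#' paired exact Wilcoxon compares the amplitude between the lowest- and
#' highest-repeat-frequency conditions. The report records every threshold
#' applied and the configuration hash; identical configurations give
#' identical reports.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, `report.json`,
#'   `metrics.csv` and `units.csv` are written there.
#' @return the report, a nested list (see `inst/schema/report_schema.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stim_summary <- do.call(rbind, lapply(config$stimuli, function(sp)
    data.frame(kind = sp$kind, n_sections = sp$n_sections,
               refresh_hz = sp$refresh_hz,
               repeat_hz = repeat_frequency(sp),
               repeat_hz_reported = round_half_up(repeat_frequency(sp), 1))))
  metrics <- list()
  units_rows <- list()
  for (m in seq_len(config$n_mice)) {
    for (si in seq_along(config$stimuli)) {
      sp <- config$stimuli[[si]]
      sp$n_trials <- config$n_trials
      sched <- tryCatch(build_sequential_schedule(sp),
                        error = function(e) fail("stage stimgen failed on ",
                                                 sp$kind, ": ", conditionMessage(e)))
      sc <- synthetic_config(
        n_channels = config$n_channels, hf_span_channels = config$hf_span_channels,
        hf_gain = config$hf_gain, locking_kappa = config$locking_kappa,
        n_units = config$n_units,
        rng_seed = config$seed + 1000L * m + si)
      rec <- tryCatch(generate_lfp(sc, sched),
                      error = function(e) fail("stage simulate failed on ",
                                               sp$kind, ": ", conditionMessage(e)))
      hf <- tryCatch(
        analyze_lfp_hf(rec, band = config$band, threshold = config$threshold,
                       channel_range = config$channel_range),
        error = function(e) fail("stage analyze-lfp failed on ", sp$kind,
                                 ": ", conditionMessage(e)))
      spk <- tryCatch(generate_spikes(sc, sched),
                      error = function(e) fail("stage simulate-spikes failed on ",
                                               sp$kind, ": ", conditionMessage(e)))
      f_rep <- repeat_frequency(sp)
      for (u in seq_along(spk$spikes)) {
        phs <- spike_phases(spk$spikes[[u]], f_rep, sched$events$onset_s,
                            sp$trial_duration_s)
        pr <- ppc(phs)
        units_rows[[length(units_rows) + 1L]] <- data.frame(
          mouse = m, condition = sp$kind, refresh_hz = sp$refresh_hz,
          repeat_hz = f_rep, unit_id = u, n_spikes = pr$n_spikes,
          ppc = pr$ppc)
      }
      metrics[[length(metrics) + 1L]] <- data.frame(
        mouse = m, condition = sp$kind, refresh_hz = sp$refresh_hz,
        repeat_hz = f_rep, amplitude_auc = hf$amplitude_auc,
        size_channels = hf$size$size_channels, size_um = hf$size$size_um)
    }
  }
  metrics <- do.call(rbind, metrics)
  units_df <- do.call(rbind, units_rows)

  stats_tab <- NULL
  if (config$n_mice >= 5 && length(unique(metrics$repeat_hz)) >= 2) {
    lo <- min(metrics$repeat_hz); hi <- max(metrics$repeat_hz)
    agg <- stats::aggregate(amplitude_auc ~ mouse + repeat_hz, metrics, mean)
    w <- paired_wilcoxon(a = agg$amplitude_auc[agg$repeat_hz == lo],
                         b = agg$amplitude_auc[agg$repeat_hz == hi])
    stats_tab <- list(test = "paired_wilcoxon_exact",
                      metric = "amplitude_auc",
                      cond_a = paste0(lo, " Hz"), cond_b = paste0(hi, " Hz"),
                      p = w$p, n_pairs = w$n_pairs)
  }

  report <- list(
    provenance = list(config_hash = config_hash(config), seed = config$seed,
                      package_version = as.character(utils::packageVersion("seqssvep")),
                      thresholds = list(hf_band_hz = config$band,
                                        size_threshold_au = config$threshold,
                                        responsiveness_snr = 7.5,
                                        waveform_boundary_ms = 0.43,
                                        isi_violation_max = 5e-4)),
    stimulus_set = stim_summary,
    n_distinct_repeat_frequencies = length(unique(stim_summary$repeat_hz)),
    metrics = metrics,
    ppc_by_repeat_frequency = stats::aggregate(
      ppc ~ repeat_hz, units_df[!is.na(units_df$ppc), ], mean),
    units = units_df,
    statistics = stats_tab)
  validate_report(report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(units_df, file.path(out_dir, "units.csv"),
                     row.names = FALSE)
  }
  report
}

#' Check a pipeline report against the shipped schema
#'
#' Verifies the presence and basic types of every required property of
#' `inst/schema/report_schema.json`.
#'
#' @param report a [run_pipeline()] result.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(
    system.file("schema", "report_schema.json", package = "seqssvep"),
    simplifyVector = TRUE)
  req <- schema$required
  for (k in req)
    if (is.null(report[[k]]))
      fail("report is missing required property '", k, "'")
  for (k in schema$properties$provenance$required)
    if (is.null(report$provenance[[k]]))
      fail("report provenance is missing '", k, "'")
  if (!is.data.frame(report$metrics))
    fail("report$metrics must be a table")
  invisible(TRUE)
}
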