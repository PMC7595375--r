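#' Write a trial recording to CSV
#'
#' Columns `t_s,x_hip_m,x_sho_m,torque_Nm,platform_tilt_deg`, '.' decimal
#' separator, plus a JSON metadata sidecar (`<path>.meta.json`) carrying
#' subject, condition labels, sample rate and units. Ground-truth fields of
#' synthetic recordings are not written: on disk a synthetic trial looks
#' like a real one.
#'
#' @param recording a `sway_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(recording, path) {
  df <- data.frame(t_s = recording$t,
                   x_hip_m = recording$x_hip,
                   x_sho_m = recording$x_sho,
                   torque_Nm = recording$torque,
                   platform_tilt_deg = recording$platform_tilt)
  data.table::fwrite(df, path)
  meta <- list(subject = recording$subject, visual = recording$visual,
               platform = recording$platform,
               sample_rate = recording$sample_rate,
               units = list(t = "s", x_hip = "m", x_sho = "m",
                            torque = "N*m", platform_tilt = "deg"))
  if (!is.null(recording$ground_truth$segment_break))
    meta$segment_break <- recording$ground_truth$segment_break
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a trial recording from CSV
#'
#' Inverse of [write_trial()]: validates the column schema and the
#' uniformity of the time base, and restores condition labels from the JSON
#' sidecar when present.
#'
#' @param path CSV path (gzipped accepted).
#' @return a `sway_recording`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("no such trial file: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("t_s", "x_hip_m", "x_sho_m", "torque_Nm", "platform_tilt_deg")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(path, ": missing columns: ", paste(missing, collapse = ", "))
  dtv <- diff(df$t_s)
  if (any(dtv <= 0) || (max(dtv) - min(dtv)) > 1e-9)
    stop(path, ": non-uniform time base (first offending interval after line ",
         which(abs(dtv - stats::median(dtv)) > 1e-9 | dtv <= 0)[1] + 1L, ")")
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  fs <- if (!is.null(meta$sample_rate)) meta$sample_rate else 1 / stats::median(dtv)
  if (abs(fs * stats::median(dtv) - 1) > 1e-6)
    stop(path, ": sample rate in metadata (", fs,
         " Hz) disagrees with the time column")
  gt <- if (!is.null(meta$segment_break))
    list(segment_break = as.integer(meta$segment_break)) else NULL
  new_sway_recording(
    t = df$t_s, x_hip = df$x_hip_m, x_sho = df$x_sho_m,
    torque = df$torque_Nm, platform_tilt = df$platform_tilt_deg,
    sample_rate = fs,
    visual = if (!is.null(meta$visual)) meta$visual else NA_character_,
    platform = if (!is.null(meta$platform)) meta$platform else NA_character_,
    subject = if (!is.null(meta$subject)) meta$subject else NA_character_,
    ground_truth = gt)
}

#' Fit calibration coefficients from a calibration recording
#'
#' Derives the centre of pressure from the torque channel and regresses it
#' on the sway-rod translations ([fit_calibration()]).
#'
#' @param recording a calibration `sway_recording` (platform stationary).
#' @param body_mass subject mass, kg.
#' @return a `calibration_coefficients` object.
#' @export
calibrate_recording <- function(recording, body_mass) {
  x_cop <- cop_from_torque(recording$torque, body_mass)
  fit_calibration(recording$x_hip, recording$x_sho, x_cop)
}

#' Centre-of-mass angle trace of a recording
#'
#' Applies the calibration map to the sway-rod channels and converts to an
#' angle about the ankle.
#'
#' @param recording a `sway_recording`.
#' @param coeffs `calibration_coefficients`.
#' @param h_com COM height above the ankle, m.
#' @return numeric series, theta_com in deg.
#' @export
com_trace <- function(recording, coeffs, h_com) {
  com_angle(compute_com(recording$x_hip, recording$x_sho, coeffs), h_com)
}

#' Analysis settings for [trial_metrics()] and the pipeline
#'
#' @param filter_order,filter_cutoff Butterworth order and cutoff (Hz) of
#'   the zero-phase low-pass applied to spontaneous-sway traces.
#' @param filter_tilt apply the same low-pass to tilt trials too (off by
#'   default: the published analysis filters quiet-stance and
#'   sway-referencing trials only).
#' @param discard,window spontaneous-sway discard and analysis window, s.
#' @param cycle_duration,n_cycles,discard_first tilt-trial decomposition
#'   settings.
#' @return list of settings.
#' @export
analysis_settings <- function(filter_order = 2, filter_cutoff = 5,
                              filter_tilt = FALSE,
                              discard = 15, window = 30,
                              cycle_duration = 20, n_cycles = 13,
                              discard_first = 1) {
  list(filter_order = filter_order, filter_cutoff = filter_cutoff,
       filter_tilt = filter_tilt, discard = discard, window = window,
       cycle_duration = cycle_duration, n_cycles = n_cycles,
       discard_first = discard_first)
}

#' Scalar sway outcomes of one trial
#'
#' Computes the trial's outcome parameters from its COM angle trace:
#' mean sway velocity for `fixed` and `sway_referenced` segments (the
#' combined `fixed+sway_referenced` trial is split at its segment break and
#' yields both), periodic and random sway power for `tilt` trials.
#'
#' @param recording a `sway_recording` with condition labels.
#' @param coeffs `calibration_coefficients` for the subject.
#' @param h_com COM height, m.
#' @param settings an [analysis_settings()] list.
#' @return data.frame with columns `subject`, `visual`, `platform`
#'   (outcome level: `velocity_fixed`, `velocity_swayref`,
#'   `power_periodic`, `power_random`) and `value`.
#' @export
trial_metrics <- function(recording, coeffs, h_com,
                          settings = analysis_settings()) {
  fs <- recording$sample_rate
  theta <- com_trace(recording, coeffs, h_com)
  lp <- function(x) lowpass(x, settings$filter_order, settings$filter_cutoff, fs)
  sv <- function(x) sway_velocity(lp(x), fs, settings$discard,
                                  settings$window)$sway_velocity_s
  base <- data.frame(subject = recording$subject, visual = recording$visual,
                     stringsAsFactors = FALSE)
  if (recording$platform == "tilt") {
    if (settings$filter_tilt) theta <- lp(theta)
    dec <- cycle_decompose(theta, settings$cycle_duration, settings$n_cycles,
                           fs, settings$discard_first)
    rbind(cbind(base, platform = "power_periodic", value = dec$periodic_power),
          cbind(base, platform = "power_random", value = dec$random_power))
  } else if (recording$platform == "fixed+sway_referenced") {
    brk <- recording$ground_truth$segment_break
    if (is.null(brk)) brk <- length(theta) %/% 2L + 1L
    rbind(cbind(base, platform = "velocity_fixed",
                value = sv(theta[seq_len(brk - 1L)])),
          cbind(base, platform = "velocity_swayref",
                value = sv(theta[brk:length(theta)])))
  } else if (recording$platform == "fixed") {
    cbind(base, platform = "velocity_fixed", value = sv(theta))
  } else if (recording$platform == "sway_referenced") {
    cbind(base, platform = "velocity_swayref", value = sv(theta))
  } else {
    stop("unknown platform label: ", recording$platform)
  }
}

#' Group-level statistics of an outcome table
#'
#' Normalises the outcome columns ([normalize_outcomes()]), runs the
#' combined two-way repeated-measures ANOVA, the simple contrasts against
#' the reference visual condition, and the per-platform-level post-hoc
#' analyses.
#'
#' @param outcomes long-format outcome table (`subject`, `visual`,
#'   `platform`, `value`).
#' @param reference reference visual level (default `"EO"`).
#' @param normalization `"zscore"` (default), `"log"` or `"raw"`.
#' @param exclude character vector of subject ids to exclude (explicit
#'   list; outliers are never dropped automatically).
#' @return list with `anova`, `contrasts`, `posthoc` (named list per
#'   platform level), `outcomes_normalized`, `excluded`.
#' @export
study_statistics <- function(outcomes, reference = "EO",
                             normalization = "zscore", exclude = character()) {
  if (length(exclude))
    outcomes <- outcomes[!outcomes$subject %in% exclude, , drop = FALSE]
  norm <- normalize_outcomes(outcomes, normalization)
  posthoc <- lapply(stats::setNames(nm = unique(norm$platform)), function(lev)
    single_level_posthoc(norm, lev, reference = reference))
  list(anova = rm_anova_2way(norm),
       contrasts = simple_contrasts(norm, reference = reference),
       posthoc = posthoc,
       outcomes_normalized = norm,
       excluded = exclude)
}

#' Run the full synthetic pipeline
#'
#' Simulates a study subject by subject (raw recordings are discarded after
#' analysis, bounding memory), calibrates each subject from their
#' calibration recording, computes all trial outcomes, and runs the group
#' statistics. The whole run is a pure function of `(config, n_subjects,
#' seed, settings)`.
#'
#' @param config a [sim_config()].
#' @param n_subjects number of subjects.
#' @param seed master seed.
#' @param settings [analysis_settings()].
#' @param reference,normalization,exclude passed to [study_statistics()].
#' @param out_dir optional directory; when given, `metrics.csv`,
#'   `anova.csv`, `contrasts.csv` and `run_log.json` are written there.
#' @return list with `outcomes` (raw outcome table), `stats` (see
#'   [study_statistics()]), `calibration` (per-subject fit summary),
#'   `stimulus_metadata`, `seed`.
#' @export
run_study_pipeline <- function(config = sim_config(), n_subjects = 10,
                               seed = 1, settings = analysis_settings(),
                               reference = "EO", normalization = "zscore",
                               exclude = character(), out_dir = NULL) {
  stimulus <- prts_stimulus(n_cycles = settings$n_cycles,
                            state_duration = settings$cycle_duration / 80,
                            sample_rate = config$sample_rate)
  set.seed(seed)
  trial_seeds <- matrix(sample.int(.Machine$integer.max, n_subjects * 16),
                        nrow = n_subjects)
  metric_rows <- list()
  calib_rows <- list()
  # subject loop (memory-bounded: one subject's raw data at a time)
  for (s in seq_len(n_subjects)) {
    one <- generate_subject(config, s, trial_seeds[s, ], stimulus)
    coeffs <- calibrate_recording(one$calibration, one$body_mass)
    for (rec in one$recordings)
      metric_rows[[length(metric_rows) + 1L]] <-
        trial_metrics(rec, coeffs, one$h_com, settings)
    calib_rows[[s]] <- data.frame(
      subject = one$subject, a = coeffs$a, b = coeffs$b, c = coeffs$c,
      residual_rms = coeffs$residual_rms, stringsAsFactors = FALSE)
  }
  outcomes <- do.call(rbind, metric_rows)
  stats <- study_statistics(outcomes, reference, normalization, exclude)
  result <- list(outcomes = outcomes, stats = stats,
                 calibration = do.call(rbind, calib_rows),
                 stimulus_metadata = stimulus$metadata, seed = seed)
  if (!is.null(out_dir)) write_result_bundle(result, out_dir, config)
  result
}

# one subject's jittered config + all recordings; mirrors generate_study()
generate_subject <- function(config, s, seeds, stimulus, jitter = 0.1) {
  sid <- sprintf("S%02d", s)
  set.seed(seeds[1])
  jit <- stats::runif(5, 1 - jitter, 1 + jitter)
  wj <- stats::runif(length(config$w_vis), 1 - jitter, 1 + jitter)
  w_vis_s <- config$w_vis * wj
  w_vis_s["EC"] <- 0
  # gains scale with body size (gravitational stiffness ~ mass x height) so
  # the static stability margin is jittered by jit[3:4] only
  cfg_s <- sim_config(
    body_mass = config$body_mass * jit[1],
    body_height = config$body_height * jit[2],
    kp = config$kp * jit[1] * jit[2] * jit[3],      # ~ mgh scaling
    kd = config$kd * jit[1] * jit[2]^2 * jit[4],    # ~ inertia scaling
    delay = config$delay,
    w_vis = pmin(w_vis_s, 1 - config$w_vest), w_vest = config$w_vest,
    noise_sd = config$noise_sd * jit[5], noise_cutoff = config$noise_cutoff,
    wiggle_sd = config$wiggle_sd, wiggle_cutoff = config$wiggle_cutoff,
    ankle_ratio = config$ankle_ratio,
    servo_time_constant = config$servo_time_constant,
    sample_rate = config$sample_rate,
    fall_threshold_deg = config$fall_threshold_deg,
    duration_fixed = config$duration_fixed,
    duration_swayref = config$duration_swayref,
    duration_calibration = config$duration_calibration)
  visuals <- c("EO", "LAB", "ABS", "EC")
  recs <- list()
  for (vi in seq_along(visuals)) {
    v <- visuals[vi]
    recs[[paste(sid, v, "tilt", sep = "_")]] <-
      simulate_trial(cfg_s, v, "tilt", stimulus = stimulus,
                     seed = seeds[2 + 2 * vi - 1], subject = sid)
    recs[[paste(sid, v, "stance", sep = "_")]] <-
      simulate_combined_trial(cfg_s, v, seed = seeds[2 + 2 * vi],
                              subject = sid)
  }
  list(subject = sid, body_mass = cfg_s$body_mass, h_com = cfg_s$h_com,
       config = cfg_s,
       calibration = simulate_calibration_motion(cfg_s, seed = seeds[2],
                                                 subject = sid),
       recordings = recs)
}

write_result_bundle <- function(result, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(result$outcomes, file.path(out_dir, "metrics.csv"))
  data.table::fwrite(as.data.frame(result$stats$anova),
                     file.path(out_dir, "anova.csv"))
  data.table::fwrite(as.data.frame(result$stats$contrasts),
                     file.path(out_dir, "contrasts.csv"))
  log <- list(
    package_version = as.character(utils::packageVersion("posturelab")),
    seed = result$seed,
    stimulus = result$stimulus_metadata,
    config_hash = digest_config(config),
    excluded = result$stats$excluded,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

# order-stable hash of a configuration list (no external digest dependency)
digest_config <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA)
  # polynomial rolling hash over the serialized config (fingerprint only)
  h <- 0
  for (byte in utf8ToInt(as.character(s)))
    h <- (h * 131 + byte) %% 2147483647
  sprintf("%08x", h)
}

#' Analyse a directory of recorded trials
#'
#' Disk-based entry point mirroring [run_study_pipeline()] for real (or
#' exported synthetic) data: reads a manifest CSV with columns `subject`,
#' `visual`, `platform`, `file`, `body_mass`, `h_com` and a `calibration`
#' row per subject (`platform = "calibration"`), computes all outcomes and
#' the group statistics. Input files are never modified.
#'
#' @param manifest path to the manifest CSV; `file` paths are resolved
#'   relative to the manifest's directory.
#' @param settings,reference,normalization,exclude,out_dir as in
#'   [run_study_pipeline()].
#' @return as [run_study_pipeline()] (without simulator ground truth).
#' @export
run_pipeline <- function(manifest, settings = analysis_settings(),
                         reference = "EO", normalization = "zscore",
                         exclude = character(), out_dir = NULL) {
  man <- data.table::fread(manifest, data.table = FALSE)
  need <- c("subject", "visual", "platform", "file", "body_mass", "h_com")
  if (length(setdiff(need, names(man))))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  root <- dirname(manifest)
  metric_rows <- list(); calib_rows <- list()
  for (sid in unique(man$subject)) {
    rows <- man[man$subject == sid, , drop = FALSE]
    cal_row <- rows[rows$platform == "calibration", , drop = FALSE]
    if (nrow(cal_row) != 1L)
      stop("subject ", sid, ": expected exactly one calibration row")
    cal <- read_trial(file.path(root, cal_row$file))
    coeffs <- calibrate_recording(cal, cal_row$body_mass)
    calib_rows[[sid]] <- data.frame(subject = sid, a = coeffs$a,
                                    b = coeffs$b, c = coeffs$c,
                                    residual_rms = coeffs$residual_rms)
    for (i in which(rows$platform != "calibration")) {
      rec <- read_trial(file.path(root, rows$file[i]))
      rec$subject <- sid
      rec$visual <- rows$visual[i]
      rec$platform <- rows$platform[i]
      metric_rows[[length(metric_rows) + 1L]] <- tryCatch(
        trial_metrics(rec, coeffs, rows$h_com[i], settings),
        error = function(e) stop("stage trial_metrics failed for subject ",
                                 sid, ", trial ", rows$file[i], ": ",
                                 conditionMessage(e)))
    }
  }
  outcomes <- do.call(rbind, metric_rows)
  stats <- study_statistics(outcomes, reference, normalization, exclude)
  result <- list(outcomes = outcomes, stats = stats,
                 calibration = do.call(rbind, calib_rows), seed = NA)
  if (!is.null(out_dir)) write_result_bundle(result, out_dir, list(manifest = manifest))
  result
}
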