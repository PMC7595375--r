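#' Simulator configuration for a synthetic stander
#'
#' Builds the parameter set of the feedback-controlled stander used by
#' [simulate_trial()], [simulate_calibration_motion()] and
#' [generate_study()]. The model is a single-link inverted pendulum in the
#' sagittal plane (centre-of-mass angle `theta` about the ankle) stabilised
#' by a delayed proportional-derivative ankle torque acting on a weighted
#' sensory error, with a kinematic two-segment readout that produces the
#' hip and shoulder sway-rod channels. It is a stand-in with the
#' statistical structure the analysis pipeline assumes, not a validated
#' physiological model.
#'
#' Sensory weighting: the error signal is
#' `e = w_prop * (theta_leg - theta_platform) + (w_vis + w_vest) * theta`,
#' where the proprioceptive cue is the ankle angle (leg-segment tilt minus
#' platform tilt). Per visual condition `w_vis` takes the preset value
#' (`EO` 0.35, `LAB` 0.33, `ABS` 0.15, `EC` 0), `w_vest` is fixed, and
#' `w_prop = 1 - w_vis - w_vest`, so the weights sum to one. Closing the
#' eyes or sway-referencing the platform lowers the effective feedback gain
#' and therefore increases noise-driven sway, reproducing the qualitative
#' ordering of the experimental conditions.
#'
#' @param body_mass kg.
#' @param body_height m.
#' @param leg_frac,trunk_frac segment lengths (ankle-hip, hip-shoulder) as
#'   fractions of body height.
#' @param leg_mass_frac mass fraction of the legs (remainder is the
#'   head-arms-trunk segment).
#' @param leg_com_frac,trunk_com_frac segment COM position as a fraction of
#'   segment length from the distal end.
#' @param inertia_factor moment of inertia as a multiple of
#'   `mass * h_com^2` (distributed mass > point mass).
#' @param kp,kd controller gains, N*m/rad and N*m*s/rad.
#' @param delay feedback delay, s.
#' @param w_vis named numeric, visual weight per condition.
#' @param w_vest vestibular weight (condition-independent).
#' @param noise_sd torque noise SD after low-pass filtering, N*m.
#' @param noise_cutoff torque-noise low-pass cutoff, Hz.
#' @param wiggle_sd SD of the independent hip-strategy component of the
#'   leg-segment tilt, deg (makes hip and shoulder channels linearly
#'   independent during dynamic trials).
#' @param wiggle_cutoff low-pass cutoff of the hip-strategy component, Hz.
#' @param ankle_ratio leg-tilt / COM-angle ratio of the kinematic readout.
#' @param servo_time_constant sway-referencing servo lag, s (0 = perfect
#'   tracking of the leg tilt).
#' @param sample_rate Hz.
#' @param fall_threshold_deg abort threshold on |theta|, deg.
#' @param duration_fixed,duration_swayref,duration_calibration s.
#' @return object of class `sim_config`, a list of the above plus derived
#'   quantities: segment lengths `l_leg`, `l_trunk` (m), true readout
#'   coefficients `b_true`, `c_true`, COM height `h_com` (m), inertia `J`
#'   (kg m^2), gravitational stiffness `mgh` (N*m/rad).
#' @export
sim_config <- function(body_mass = 75, body_height = 1.75,
                       leg_frac = 0.5, trunk_frac = 0.3,
                       leg_mass_frac = 0.32,
                       leg_com_frac = 0.55, trunk_com_frac = 0.40,
                       inertia_factor = 1.2,
                       kp = 2800, kd = 700, delay = 0.1,
                       w_vis = c(EO = 0.35, LAB = 0.33, ABS = 0.15, EC = 0),
                       w_vest = 0.35,
                       noise_sd = 9, noise_cutoff = 0.5,
                       wiggle_sd = 0.3, wiggle_cutoff = 0.3,
                       ankle_ratio = 0.8,
                       servo_time_constant = 0,
                       sample_rate = 1000,
                       fall_threshold_deg = 10,
                       duration_fixed = 45, duration_swayref = 45,
                       duration_calibration = 120) {
  stopifnot(body_mass > 0, body_height > 0, kp > 0, kd >= 0, delay >= 0,
            w_vest >= 0, all(w_vis >= 0), all(w_vis + w_vest <= 1),
            noise_sd >= 0, servo_time_constant >= 0, sample_rate > 0)
  l_leg <- leg_frac * body_height
  l_trunk <- trunk_frac * body_height
  hat_mass_frac <- 1 - leg_mass_frac
  b_true <- leg_mass_frac * leg_com_frac + hat_mass_frac * (1 - trunk_com_frac)
  c_true <- hat_mass_frac * trunk_com_frac
  h_com <- b_true * l_leg + c_true * (l_leg + l_trunk)
  g <- 9.81
  cfg <- list(
    body_mass = body_mass, body_height = body_height,
    l_leg = l_leg, l_trunk = l_trunk,
    b_true = b_true, c_true = c_true, h_com = h_com,
    J = inertia_factor * body_mass * h_com^2,
    mgh = body_mass * g * h_com, g = g,
    kp = kp, kd = kd, delay = delay,
    w_vis = w_vis, w_vest = w_vest,
    noise_sd = noise_sd, noise_cutoff = noise_cutoff,
    wiggle_sd = wiggle_sd, wiggle_cutoff = wiggle_cutoff,
    ankle_ratio = ankle_ratio,
    servo_time_constant = servo_time_constant,
    sample_rate = sample_rate,
    fall_threshold_deg = fall_threshold_deg,
    duration_fixed = duration_fixed, duration_swayref = duration_swayref,
    duration_calibration = duration_calibration)
  class(cfg) <- "sim_config"
  cfg
}

# seed-reproducible band-limited noise with a given post-filter SD;
# generous burn-in margins are discarded because zero-phase edge
# initialisation assumes a locally smooth signal, which white noise is not
filtered_noise <- function(n, sd_target, cutoff, sample_rate) {
  if (sd_target == 0 || n < 8L) return(numeric(n))
  burn <- as.integer(ceiling(5 * sample_rate / cutoff))
  x <- lowpass(stats::rnorm(n + 2L * burn), order = 2, cutoff = cutoff,
               sample_rate = sample_rate)
  x <- x[(burn + 1L):(burn + n)]
  x * (sd_target / stats::sd(x))
}

new_sway_recording <- function(t, x_hip, x_sho, torque, platform_tilt,
                               sample_rate, visual, platform,
                               subject = "S01", ground_truth = NULL) {
  structure(list(t = t, x_hip = x_hip, x_sho = x_sho, torque = torque,
                 platform_tilt = platform_tilt, sample_rate = sample_rate,
                 visual = visual, platform = platform, subject = subject,
                 ground_truth = ground_truth),
            class = "sway_recording")
}

#' @export
print.sway_recording <- function(x, ...) {
  cat(sprintf(
    "sway_recording: subject %s, visual %s, platform %s\n  %d samples at %g Hz (%.4g s)\n",
    x$subject, x$visual, x$platform, length(x$t), x$sample_rate,
    length(x$t) / x$sample_rate))
  invisible(x)
}

#' Sway-referencing servo response
#'
#' First-order lag tracking of the leg-segment tilt, the stand-in for the
#' platform servo in the sway-referenced condition: the platform follows the
#' leg tilt with time constant `time_constant`, so at `time_constant = 0`
#' the platform tilt equals the leg tilt at every sample and the ankle angle
#' (leg tilt minus platform tilt) never changes.
#'
#' @param theta_leg numeric leg-tilt series (deg).
#' @param time_constant servo time constant, s (>= 0).
#' @param sample_rate Hz.
#' @return platform tilt series (deg), same length.
#' @export
sway_reference_servo <- function(theta_leg, time_constant, sample_rate) {
  if (time_constant < 0) stop("`time_constant` must be >= 0")
  alpha <- if (time_constant == 0) 1 else 1 - exp(-1 / (sample_rate * time_constant))
  iir_filter(alpha, c(1, -(1 - alpha)), theta_leg, numeric(1))
}

# two-segment kinematic readout: given COM angle (rad) and leg tilt (rad),
# return hip/shoulder translations consistent with x_com = b*x_hip + c*x_sho
readout_channels <- function(theta, theta_leg, cfg) {
  x_com <- cfg$h_com * sin(theta)
  x_hip <- cfg$l_leg * sin(theta_leg)
  x_sho <- (x_com - cfg$b_true * x_hip) / cfg$c_true
  list(x_com = x_com, x_hip = x_hip, x_sho = x_sho)
}

#' Simulate one standing-balance trial
#'
#' Integrates the closed-loop inverted pendulum of [sim_config()] under one
#' visual condition and one platform mode, and returns the multichannel
#' recording a real rig would produce (hip and shoulder sway-rod
#' translations, ankle torque, platform tilt) plus the simulator's ground
#' truth. Deterministic given `(config, visual, platform, stimulus, seed)`.
#'
#' @param config a `sim_config`.
#' @param visual one of `"EO"`, `"LAB"`, `"ABS"`, `"EC"`.
#' @param platform one of `"fixed"`, `"sway_referenced"`, `"tilt"`.
#' @param stimulus a `tilt_stimulus` (required iff `platform = "tilt"`).
#' @param seed integer RNG seed.
#' @param duration trial length in s; defaults to the configured duration
#'   for the platform mode (stimulus length for tilt trials).
#' @param subject subject label.
#' @param init optional list(theta, omega) initial state in rad, rad/s
#'   (used to chain trial segments).
#' @return a `sway_recording`; its `ground_truth` holds `theta_com` (deg),
#'   `x_com` (m), the readout coefficients and the sensory weights used.
#' @export
simulate_trial <- function(config, visual = "EO",
                           platform = c("fixed", "sway_referenced", "tilt"),
                           stimulus = NULL, seed = 1, duration = NULL,
                           subject = "S01", init = NULL) {
  platform <- match.arg(platform)
  if (!visual %in% names(config$w_vis))
    stop("unknown visual condition: ", visual)
  if (platform == "tilt" && is.null(stimulus))
    stop("a tilt stimulus is required when platform = 'tilt'")
  if (platform != "tilt" && !is.null(stimulus))
    stop("a stimulus is only meaningful when platform = 'tilt'")
  fs <- config$sample_rate
  dt <- 1 / fs
  if (is.null(duration)) {
    duration <- switch(platform,
                       fixed = config$duration_fixed,
                       sway_referenced = config$duration_swayref,
                       tilt = length(stimulus$tilt_full) / stimulus$sample_rate)
  }
  n <- round(duration * fs)
  stim_rad <- if (platform == "tilt") {
    if (stimulus$sample_rate != fs)
      stop("stimulus sample rate must match the recording sample rate")
    if (length(stimulus$tilt_full) < n)
      stop("stimulus shorter than requested trial duration")
    stimulus$tilt_full[seq_len(n)] * pi / 180
  } else numeric(0)

  w_vis <- unname(config$w_vis[[visual]])
  w_prop <- 1 - w_vis - config$w_vest
  w_vv <- w_vis + config$w_vest

  set.seed(seed)
  noise <- filtered_noise(n, config$noise_sd, config$noise_cutoff, fs)
  wiggle <- filtered_noise(n, config$wiggle_sd * pi / 180,
                           config$wiggle_cutoff, fs)
  alpha <- if (config$servo_time_constant == 0) 1 else
    1 - exp(-dt / config$servo_time_constant)
  mode <- match(platform, c("fixed", "sway_referenced", "tilt")) - 1L
  theta0 <- if (is.null(init)) 0 else init$theta
  omega0 <- if (is.null(init)) 0 else init$omega
  out <- simulate_pendulum_cpp(
    n = n, dt = dt, J = config$J, mgh = config$mgh,
    Kp = config$kp, Kd = config$kd,
    delay_steps = as.integer(round(config$delay * fs)),
    w_prop = w_prop, w_vv = w_vv, r_ankle = config$ankle_ratio,
    platform_mode = mode, servo_alpha = alpha,
    stimulus = stim_rad, wiggle = wiggle, noise = noise,
    theta0 = theta0, omega0 = omega0,
    fall_threshold = config$fall_threshold_deg * pi / 180)

  theta_leg <- config$ankle_ratio * out$theta + wiggle
  ch <- readout_channels(out$theta, theta_leg, config)
  new_sway_recording(
    t = (seq_len(n) - 1L) * dt,
    x_hip = ch$x_hip, x_sho = ch$x_sho, torque = out$torque,
    platform_tilt = out$theta_platform * 180 / pi,
    sample_rate = fs, visual = visual, platform = platform,
    subject = subject,
    ground_truth = list(
      theta_com = out$theta * 180 / pi, x_com = ch$x_com,
      theta_leg = theta_leg * 180 / pi,
      omega = out$omega,
      a_true = 0, b_true = config$b_true, c_true = config$c_true,
      h_com = config$h_com,
      weights = c(w_vis = w_vis, w_prop = w_prop, w_vest = config$w_vest),
      final_state = list(theta = out$theta[n], omega = out$omega[n])))
}

#' Simulate the combined quiet-stance / sway-referenced trial
#'
#' The experiment measured quiet stance on a fixed surface immediately
#' followed by the sway-referenced condition in a single trial. This helper
#' chains the two segments (the second starts from the final state of the
#' first) and returns one recording labelled
#' `"fixed+sway_referenced"`.
#'
#' @inheritParams simulate_trial
#' @return a `sway_recording` of duration `duration_fixed +
#'   duration_swayref`; `ground_truth$segment_break` gives the index of the
#'   first sway-referenced sample.
#' @export
simulate_combined_trial <- function(config, visual = "EO", seed = 1,
                                    subject = "S01") {
  r1 <- simulate_trial(config, visual, "fixed", seed = seed,
                       subject = subject)
  r2 <- simulate_trial(config, visual, "sway_referenced",
                       seed = (seed %% 1000000000L) + 1L,
                       subject = subject,
                       init = r1$ground_truth$final_state)
  n1 <- length(r1$t)
  gt <- list(theta_com = c(r1$ground_truth$theta_com, r2$ground_truth$theta_com),
             x_com = c(r1$ground_truth$x_com, r2$ground_truth$x_com),
             a_true = 0, b_true = config$b_true, c_true = config$c_true,
             h_com = config$h_com,
             weights = r1$ground_truth$weights,
             segment_break = n1 + 1L)
  new_sway_recording(
    t = c(r1$t, r1$t[n1] + 1 / config$sample_rate + r2$t),
    x_hip = c(r1$x_hip, r2$x_hip), x_sho = c(r1$x_sho, r2$x_sho),
    torque = c(r1$torque, r2$torque),
    platform_tilt = c(r1$platform_tilt, r2$platform_tilt),
    sample_rate = config$sample_rate, visual = visual,
    platform = "fixed+sway_referenced", subject = subject,
    ground_truth = gt)
}

#' Simulate the quasi-static calibration motion
#'
#' Emulates the 120-s calibration routine: prescribed very slow sinusoidal
#' ankle and hip movements (incommensurate frequencies, defaults 0.02 and
#' 0.035 Hz) spanning the typical sway range. The torque channel is computed
#' by single-pendulum inverse dynamics, so the centre of pressure derived
#' from it matches the centre-of-mass projection up to the inertial term,
#' which scales with movement frequency squared and is negligible at these
#' frequencies (the quasi-static regime the calibration relies on).
#'
#' @param config a `sim_config`.
#' @param duration s (default `config$duration_calibration`).
#' @param seed integer; jitters the movement amplitudes and phases.
#' @param f_leg,f_trunk movement frequencies, Hz.
#' @param amp_leg,amp_trunk movement amplitudes, deg.
#' @param subject subject label.
#' @return a `sway_recording` with `platform = "fixed"` and
#'   `visual = "calibration"`.
#' @export
simulate_calibration_motion <- function(config, duration = NULL, seed = 1,
                                        f_leg = 0.02, f_trunk = 0.035,
                                        amp_leg = 1.5, amp_trunk = 2,
                                        subject = "S01") {
  if (is.null(duration)) duration <- config$duration_calibration
  if (duration <= 0) stop("`duration` must be > 0")
  fs <- config$sample_rate
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  set.seed(seed)
  jit <- stats::runif(4, 0.9, 1.1)
  phases <- stats::runif(2, 0, 2 * pi)
  th_leg <- amp_leg * jit[1] * pi / 180 * sin(2 * pi * f_leg * jit[3] * t + phases[1])
  th_trunk <- amp_trunk * jit[2] * pi / 180 * sin(2 * pi * f_trunk * jit[4] * t + phases[2])
  x_hip <- config$l_leg * sin(th_leg)
  x_sho <- x_hip + config$l_trunk * sin(th_trunk)
  x_com <- config$b_true * x_hip + config$c_true * x_sho
  theta_com <- asin(x_com / config$h_com)
  # inverse dynamics: T = m g x_com - J * theta_com''  (second differences)
  acc <- c(0, diff(diff(theta_com)), 0) * fs^2
  torque <- config$body_mass * config$g * x_com - config$J * acc
  new_sway_recording(
    t = t, x_hip = x_hip, x_sho = x_sho, torque = torque,
    platform_tilt = numeric(n), sample_rate = fs,
    visual = "calibration", platform = "fixed", subject = subject,
    ground_truth = list(theta_com = theta_com * 180 / pi, x_com = x_com,
                        a_true = 0, b_true = config$b_true,
                        c_true = config$c_true, h_com = config$h_com))
}

#' Generate a full synthetic study
#'
#' Simulates `n_subjects` standers through the complete experimental design:
#' one calibration recording per subject plus, per visual condition (EO,
#' LAB, ABS, EC), one pseudo-random tilt trial and one combined
#' fixed/sway-referenced trial — 2 recordings per subject and visual
#' condition. Anthropometrics, controller gains, noise level and visual
#' weights are jittered multiplicatively per subject (default +/-10%,
#' uniform); weights are renormalised to sum to one and `w_vis` stays 0 for
#' EC. Every recording is a pure function of `(config, seed)`.
#'
#' @param config a `sim_config` (the population-level defaults).
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer master seed; per-subject and per-trial seeds are
#'   derived from it.
#' @param jitter multiplicative jitter half-width (default 0.1).
#' @param stimulus optional `tilt_stimulus`; default [prts_stimulus()].
#' @return list with `recordings` (named list of `sway_recording`s,
#'   `"S01_EO_tilt"` etc.), `calibrations` (one per subject),
#'   `ground_truth` (data.frame: subject anthropometrics, gains and per
#'   condition sensory weights), `stimulus`, `config`, `seed`.
#' @export
generate_study <- function(config = sim_config(), n_subjects = 10, seed = 1,
                           jitter = 0.1, stimulus = NULL) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2")
  if (is.null(stimulus))
    stimulus <- prts_stimulus(sample_rate = config$sample_rate)
  set.seed(seed)
  trial_seeds <- matrix(sample.int(.Machine$integer.max, n_subjects * 16),
                        nrow = n_subjects)
  recordings <- list()
  calibrations <- list()
  gt_rows <- list()
  for (s in seq_len(n_subjects)) {
    one <- generate_subject(config, s, trial_seeds[s, ], stimulus,
                            jitter = jitter)
    cfg_s <- one$config
    calibrations[[one$subject]] <- one$calibration
    recordings <- c(recordings, one$recordings)
    gt_rows[[s]] <- data.frame(
      subject = one$subject, body_mass = cfg_s$body_mass,
      body_height = cfg_s$body_height, h_com = cfg_s$h_com,
      b_true = cfg_s$b_true, c_true = cfg_s$c_true,
      kp = cfg_s$kp, kd = cfg_s$kd, noise_sd = cfg_s$noise_sd,
      w_vis_EO = unname(cfg_s$w_vis["EO"]),
      w_vis_LAB = unname(cfg_s$w_vis["LAB"]),
      w_vis_ABS = unname(cfg_s$w_vis["ABS"]),
      w_vis_EC = unname(cfg_s$w_vis["EC"]),
      w_vest = cfg_s$w_vest,
      stringsAsFactors = FALSE)
  }
  list(recordings = recordings, calibrations = calibrations,
       ground_truth = do.call(rbind, gt_rows),
       stimulus = stimulus, config = config, seed = seed)
}
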