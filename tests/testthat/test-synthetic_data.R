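test_that("equilibrium without noise stays perfectly still", {
  cfg <- quick_cfg(noise_sd = 0, wiggle_sd = 0)
  rec <- simulate_trial(cfg, "EO", "fixed", seed = 1, duration = 5)
  expect_equal(rec$x_hip, rep(0, 5000))
  expect_equal(rec$x_sho, rep(0, 5000))
  expect_equal(rec$torque, rep(0, 5000))
  expect_equal(rec$ground_truth$theta_com, rep(0, 5000))
})

test_that("recordings are a pure function of (config, seed)", {
  cfg <- quick_cfg()
  r1 <- simulate_trial(cfg, "ABS", "fixed", seed = 99, duration = 4)
  r2 <- simulate_trial(cfg, "ABS", "fixed", seed = 99, duration = 4)
  expect_identical(r1, r2)
  r3 <- simulate_trial(cfg, "ABS", "fixed", seed = 100, duration = 4)
  expect_false(identical(r1$torque, r3$torque))
})

test_that("channel geometry is internally consistent", {
  cfg <- quick_cfg()
  rec <- simulate_trial(cfg, "EO", "fixed", seed = 3, duration = 4)
  # x_com = b * x_hip + c * x_sho by construction of the readout
  expect_equal(cfg$b_true * rec$x_hip + cfg$c_true * rec$x_sho,
               rec$ground_truth$x_com, tolerance = 1e-12)
  expect_equal(length(rec$t), 4 * cfg$sample_rate)
  expect_equal(diff(rec$t)[1], 1 / cfg$sample_rate)
})

test_that("closing the eyes increases sway under identical noise", {
  cfg <- quick_cfg()
  sv <- function(v) {
    rec <- simulate_trial(cfg, v, "fixed", seed = 11, duration = 20)
    th <- lowpass(rec$ground_truth$theta_com, 2, 5, cfg$sample_rate)
    sway_velocity(th, cfg$sample_rate, discard = 4, window = 10)$sway_velocity_s
  }
  expect_gt(sv("EC"), sv("EO"))
})

test_that("sway referencing increases sway for every visual preset", {
  cfg <- quick_cfg()
  for (v in c("EO", "LAB", "ABS", "EC")) {
    ratio <- sapply(1:3, function(s) {
      fx <- simulate_trial(cfg, v, "fixed", seed = 1000 + s, duration = 20)
      sr <- simulate_trial(cfg, v, "sway_referenced", seed = 2000 + s,
                           duration = 20)
      g <- function(r) sway_velocity(
        lowpass(r$ground_truth$theta_com, 2, 5, cfg$sample_rate),
        cfg$sample_rate, discard = 4, window = 10)$sway_velocity_s
      g(sr) / g(fx)
    })
    expect_gt(mean(ratio), 1)
  }
})

test_that("shifting visual weight to vestibular leaves fixed-surface gain intact", {
  # vision and vestibular cues both sense body-in-space: moving weight
  # between them must not reduce sway (here: leaves it identical)
  sv <- function(w_vis, w_vest) {
    cfg <- quick_cfg(w_vis = c(EO = w_vis, LAB = 0.3, ABS = 0.15, EC = 0),
                     w_vest = w_vest)
    rec <- simulate_trial(cfg, "EO", "fixed", seed = 5, duration = 20)
    sway_velocity(rec$ground_truth$theta_com, cfg$sample_rate,
                  discard = 4, window = 10)$sway_velocity_s
  }
  s_hi <- sv(0.35, 0.35)
  for (dw in c(0.1, 0.2, 0.35)) {
    expect_gte(sv(0.35 - dw, 0.35 + dw), s_hi - 1e-12)
  }
})

test_that("servo tracking: first-order step response and tau = 0 identity", {
  x <- c(rep(0, 100), rep(1, 3000))
  expect_equal(sway_reference_servo(x, 0, 1000), x)
  y <- sway_reference_servo(x, 0.5, 1000)
  # 63.2 % rise one time constant after the step
  expect_equal(y[100 + 500], 1 - exp(-1), tolerance = 0.01)
  expect_error(sway_reference_servo(x, -1, 1000), ">= 0")
})

test_that("perfect sway referencing freezes the ankle angle", {
  cfg <- quick_cfg(servo_time_constant = 0)
  rec <- simulate_trial(cfg, "EC", "sway_referenced", seed = 21, duration = 10)
  ankle <- rec$ground_truth$theta_leg - rec$platform_tilt
  expect_lt(max(abs(ankle - ankle[1])), 1e-9)
})

test_that("tilt trials follow the stimulus and need one", {
  cfg <- quick_cfg()
  stim <- short_stimulus()
  rec <- simulate_trial(cfg, "EO", "tilt", stimulus = stim, seed = 31)
  expect_equal(length(rec$t), length(stim$tilt_full))
  expect_equal(rec$platform_tilt, stim$tilt_full, tolerance = 1e-9)
  expect_error(simulate_trial(cfg, "EO", "tilt", seed = 1), "required")
  expect_error(simulate_trial(cfg, "EO", "fixed", stimulus = stim, seed = 1),
               "only meaningful")
})

test_that("periodic response grows with proprioceptive weight", {
  stim <- short_stimulus(n_cycles = 6)
  pow <- sapply(c(0.10, 0.45), function(w_vest) {
    cfg <- quick_cfg(w_vis = c(EO = 0.35, LAB = 0.33, ABS = 0.15, EC = 0),
                     w_vest = w_vest)   # lower w_vest => higher w_prop
    rec <- simulate_trial(cfg, "EO", "tilt", stimulus = stim, seed = 41)
    dec <- cycle_decompose(rec$ground_truth$theta_com, 4, 6,
                           cfg$sample_rate, discard_first = 1)
    dec$periodic_power
  })
  expect_gt(pow[1], pow[2])
})

test_that("unstable configurations fail with a fall error, not nonsense", {
  cfg <- quick_cfg(kp = 300)    # below gravitational stiffness
  expect_error(simulate_trial(cfg, "EO", "fixed", seed = 1, duration = 10),
               "fell at t")
})

test_that("calibration motion is quasi-static with recoverable coefficients", {
  cfg <- quick_cfg()
  cal <- simulate_calibration_motion(cfg, duration = 120, seed = 51)
  expect_equal(length(cal$t), 120000)
  x_cop <- cop_from_torque(cal$torque, cfg$body_mass)
  x_com <- cal$ground_truth$x_com
  # quasi-static regime: COP tracks COM within 1 % of the sway range
  rms <- sqrt(mean((x_cop - x_com)^2))
  expect_lt(rms, 0.01 * diff(range(x_com)))
  fit <- fit_calibration(cal$x_hip, cal$x_sho, x_cop)
  expect_equal(fit$b, cfg$b_true, tolerance = 0.01)
  expect_equal(fit$c, cfg$c_true, tolerance = 0.01)
  expect_equal(fit$a, 0, tolerance = 1e-4)
})

test_that("COP-COM discrepancy is far larger in dynamic trials", {
  cfg <- quick_cfg()
  cal <- simulate_calibration_motion(cfg, duration = 60, seed = 61)
  dyn <- simulate_trial(cfg, "EO", "tilt", stimulus = short_stimulus(),
                        seed = 61)
  nrms <- function(rec) {
    x_cop <- cop_from_torque(rec$torque, cfg$body_mass)
    d <- x_cop - rec$ground_truth$x_com
    sqrt(mean(d^2)) / diff(range(rec$ground_truth$x_com))
  }
  expect_gt(nrms(dyn) / nrms(cal), 10)
})

test_that("calibration + dynamic trial round trip recovers true COM sway", {
  cfg <- quick_cfg()
  cal <- simulate_calibration_motion(cfg, duration = 60, seed = 71)
  coeffs <- calibrate_recording(cal, cfg$body_mass)
  dyn <- simulate_trial(cfg, "EC", "fixed", seed = 72, duration = 20)
  x_rec <- compute_com(dyn$x_hip, dyn$x_sho, coeffs)
  err <- sqrt(mean((x_rec - dyn$ground_truth$x_com)^2))
  expect_lt(err, 0.01 * diff(range(dyn$ground_truth$x_com)))
  # and the angle trace matches ground truth
  th <- com_angle(x_rec, cfg$h_com)
  expect_equal(th, dyn$ground_truth$theta_com, tolerance = 1e-2)
})

test_that("generate_study delivers the full design deterministically", {
  cfg <- quick_cfg(duration_fixed = 3, duration_swayref = 3,
                   duration_calibration = 10)
  stim <- short_stimulus(n_cycles = 2)
  st1 <- generate_study(cfg, n_subjects = 3, seed = 8, stimulus = stim)
  expect_length(st1$recordings, 3 * 4 * 2)
  expect_length(st1$calibrations, 3)
  expect_setequal(
    unique(sub("^S\\d+_", "", names(st1$recordings))),
    as.vector(outer(c("EO", "LAB", "ABS", "EC"), c("tilt", "stance"),
                    paste, sep = "_")))
  st2 <- generate_study(cfg, n_subjects = 3, seed = 8, stimulus = stim)
  expect_identical(st1$ground_truth, st2$ground_truth)
  expect_identical(st1$recordings[[5]], st2$recordings[[5]])
  # jittered anthropometrics differ across subjects but stay within 10 %
  expect_gt(length(unique(st1$ground_truth$body_mass)), 1)
  expect_true(all(abs(st1$ground_truth$body_mass / cfg$body_mass - 1) <= 0.1))
  expect_true(all(st1$ground_truth$w_vis_EC == 0))
  expect_error(generate_study(cfg, n_subjects = 1), ">= 2")
})
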