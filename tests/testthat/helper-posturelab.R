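# shared fixtures, built in code at test time

# short stimulus for fast tilt-trial tests: 80 states x 0.05 s = 4-s cycle
short_stimulus <- function(n_cycles = 4, sample_rate = 1000) {
  prts_stimulus(state_duration = 0.05, n_cycles = n_cycles,
                sample_rate = sample_rate)
}

# quick simulator configuration: shorter trials, coarser durations
quick_cfg <- function(...) {
  args <- utils::modifyList(
    list(duration_fixed = 20, duration_swayref = 20,
         duration_calibration = 40),
    list(...))
  do.call(sim_config, args)
}

# short-window analysis settings matched to quick_cfg / short_stimulus
quick_settings <- function() {
  analysis_settings(discard = 4, window = 10, cycle_duration = 4,
                    n_cycles = 4)
}

# balanced within-subject outcome table with seeded random values
random_outcome_table <- function(n_subjects = 9,
                                 visual = c("EO", "LAB", "ABS", "EC"),
                                 platform = paste0("P", 1:4),
                                 seed = 42, effect = 0.3) {
  set.seed(seed)
  tab <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                     visual = visual, platform = platform,
                     stringsAsFactors = FALSE)
  tab$value <- stats::rnorm(nrow(tab)) +
    effect * match(tab$visual, unique(visual))
  tab
}

# independent oracle: base-R aov() with Error() strata
aov_oracle <- function(tab) {
  tab$subject <- factor(tab$subject)
  tab$visual <- factor(tab$visual)
  tab$platform <- factor(tab$platform)
  summary(stats::aov(value ~ visual * platform +
                       Error(subject / (visual * platform)), data = tab))
}

# pull (df, F, p) for one effect out of the aov() oracle summary
aov_effect <- function(fit, stratum, effect) {
  s <- fit[[paste0("Error: ", stratum)]][[1]]
  i <- grep(effect, trimws(rownames(s)), fixed = TRUE)[1]
  c(df = s$Df[i], F = s$`F value`[i], p = s$`Pr(>F)`[i])
}
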