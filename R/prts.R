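#' Pseudo-random ternary sequences from a GF(3) shift register
#'
#' Generates one period of a ternary maximal-length sequence (m-sequence)
#' using a linear feedback shift register over the field GF(3). The next
#' symbol is `sum(feedback_taps * state) mod 3`; the register then shifts the
#' new symbol in. For primitive feedback taps the state sequence visits every
#' nonzero register state, so the period is `3^stages - 1` and each nonzero
#' symbol occurs `3^(stages-1)` times while the zero symbol occurs
#' `3^(stages-1) - 1` times.
#'
#' @param stages register length (positive integer).
#' @param feedback_taps integer vector of length `stages` with values in
#'   0..2, the GF(3) feedback coefficients (newest state element first).
#' @param initial_state integer vector of length `stages` with values in
#'   0..2, not all zero.
#' @return an object of class `ternary_sequence`: a list with `symbols`
#'   (integer vector over \{0,1,2\}, one full period), `stages`,
#'   `feedback_taps`, `initial_state`, `period`.
#' @examples
#' s <- generate_ternary_mls(4, c(0, 0, 2, 1), c(0, 0, 0, 1))
#' length(s$symbols)  # 80
#' table(s$symbols)   # 26 zeros, 27 of each nonzero symbol
#' @export
generate_ternary_mls <- function(stages, feedback_taps, initial_state) {
  stages <- as.integer(stages)
  if (length(stages) != 1L || is.na(stages) || stages < 1L)
    stop("`stages` must be a positive integer")
  feedback_taps <- as.integer(feedback_taps) %% 3L
  initial_state <- as.integer(initial_state) %% 3L
  if (length(feedback_taps) != stages)
    stop("`feedback_taps` must have length `stages`")
  if (length(initial_state) != stages)
    stop("`initial_state` must have length `stages`")
  if (all(initial_state == 0L))
    stop("`initial_state` must not be the all-zero state")

  full_period <- 3L^stages - 1L
  state <- initial_state
  start_key <- paste(state, collapse = "")
  symbols <- integer(full_period)
  period <- NA_integer_
  for (i in seq_len(full_period)) {
    s <- sum(feedback_taps * state) %% 3L
    symbols[i] <- s
    state <- c(s, state[-stages])
    if (paste(state, collapse = "") == start_key) {
      period <- i
      break
    }
  }
  if (is.na(period) || period < full_period)
    stop(sprintf(
      "feedback taps are not primitive: attained period %d < %d = 3^%d - 1",
      if (is.na(period)) full_period + 1L else period, full_period, stages))

  structure(
    list(symbols = symbols, stages = stages, feedback_taps = feedback_taps,
         initial_state = initial_state, period = period),
    class = "ternary_sequence")
}

#' Map a ternary sequence onto platform tilt velocities
#'
#' Each symbol of the sequence becomes one velocity state: `+v_peak`, `0` or
#' `-v_peak` deg/s according to `mapping`, a bijection of \{0,1,2\} onto
#' \{+1,0,-1\}. With the default mapping the zero symbol is the zero-velocity
#' state and the two nonzero symbols take opposite signs, so over one
#' m-sequence period the velocities sum to zero (27 positive and 27 negative
#' states) and the integrated tilt returns to its starting value.
#'
#' @param seq a `ternary_sequence` or a plain integer vector over \{0,1,2\}.
#' @param v_peak velocity magnitude in deg/s (default 1.78).
#' @param mapping named numeric vector giving the sign for symbols
#'   "0", "1", "2"; must be a bijection onto \{-1, 0, +1\}.
#' @return numeric vector of velocities in deg/s.
#' @export
sequence_to_velocity <- function(seq, v_peak = 1.78,
                                 mapping = c("0" = 0, "1" = 1, "2" = -1)) {
  symbols <- if (inherits(seq, "ternary_sequence")) seq$symbols else as.integer(seq)
  if (any(!symbols %in% 0:2)) stop("symbols must be in {0, 1, 2}")
  if (length(mapping) != 3L || !setequal(names(mapping), c("0", "1", "2")) ||
      !setequal(mapping, c(-1, 0, 1)))
    stop("`mapping` must be a bijection of symbols {0,1,2} onto {-1,0,+1}")
  if (!is.numeric(v_peak) || length(v_peak) != 1L || v_peak < 0)
    stop("`v_peak` must be a single non-negative number")
  unname(v_peak * mapping[as.character(symbols)])
}

#' Integrate velocity states into a platform tilt trace
#'
#' The platform tilt angle follows the time integral of the piecewise
#' constant state velocities. The integral of a constant is linear, so the
#' trace is piecewise linear, sampled at `sample_rate`. Sample `i` holds the
#' tilt at time `(i-1)/sample_rate`; the trace covers `[0, n_states *
#' state_duration)` and, for a zero-sum velocity sequence, ends one sample
#' short of returning exactly to the start value so that concatenated cycles
#' are continuous.
#'
#' @param velocity_states numeric vector, deg/s per state.
#' @param state_duration state length in s (default 0.25).
#' @param sample_rate sampling rate in Hz (default 1000); `state_duration *
#'   sample_rate` must be a whole number of samples.
#' @return numeric vector of tilt angles in deg, length
#'   `length(velocity_states) * state_duration * sample_rate`.
#' @export
integrate_tilt <- function(velocity_states, state_duration = 0.25,
                           sample_rate = 1000) {
  sps <- state_duration * sample_rate
  if (abs(sps - round(sps)) > 1e-9)
    stop(sprintf("state_duration * sample_rate = %g is not an integer number of samples per state", sps))
  sps <- as.integer(round(sps))
  dt <- 1 / sample_rate
  # tilt at the start of each state = cumulative integral of previous states
  state_start <- c(0, cumsum(velocity_states * state_duration))
  within <- (seq_len(sps) - 1L) * dt
  tilt <- rep(state_start[seq_along(velocity_states)], each = sps) +
    rep(velocity_states, each = sps) * rep(within, times = length(velocity_states))
  tilt
}

#' Concatenate stimulus cycles into a full trial trace
#'
#' @param tilt_cycle numeric tilt trace of one cycle (deg).
#' @param n_cycles number of repetitions (>= 1).
#' @return numeric vector of length `n_cycles * length(tilt_cycle)`.
#' @export
concatenate_cycles <- function(tilt_cycle, n_cycles) {
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) stop("`n_cycles` must be >= 1")
  rep(tilt_cycle, times = n_cycles)
}

# Enumerate degree-`stages` monic GF(3) feedback tap sets in lexicographic
# order (c1, c2, ..., c_stages), c_stages != 0, and return the primitive ones.
primitive_tap_sets <- function(stages = 4L) {
  combos <- as.matrix(expand.grid(rep(list(0:2), stages), KEEP.OUT.ATTRS = FALSE))
  combos <- combos[, rev(seq_len(stages)), drop = FALSE]  # c1 varies slowest
  combos <- combos[combos[, stages] != 0, , drop = FALSE]
  ord <- do.call(order, as.data.frame(combos))
  combos <- combos[ord, , drop = FALSE]
  keep <- apply(combos, 1L, function(taps) {
    !inherits(try(generate_ternary_mls(stages, taps, c(rep(0L, stages - 1L), 1L)),
                  silent = TRUE), "try-error")
  })
  unname(lapply(which(keep), function(i) as.integer(combos[i, ])))
}

#' Build the pseudo-random ternary tilt stimulus
#'
#' Constructs the support-surface tilt stimulus used in the tilt-platform
#' condition: a ternary m-sequence of velocity states (`+v_peak`, 0,
#' `-v_peak` deg/s, each held for `state_duration` s) integrated into a
#' piecewise-linear tilt trace, repeated `n_cycles` times. Defaults give the
#' published geometry: 80 states of 0.25 s at +/-1.78 deg/s (a 20-s cycle),
#' 13 cycles (260 s), and a peak-to-peak tilt amplitude of 4 deg.
#'
#' When `feedback_taps` is `NULL` the generator searches 4-stage primitive
#' GF(3) tap sets in a canonical (lexicographic) order, with the canonical
#' initial state `(0,0,0,1)` and the canonical balanced symbol mapping
#' `0 -> 0, 1 -> +1, 2 -> -1`, and ships the first configuration whose
#' integrated cycle has a cumulative-sum range of 9 state units, the range
#' that reproduces the published 4 deg amplitude (9 x 1.78 deg/s x 0.25 s =
#' 4.005 deg; no configuration on this grid gives exactly 4). The chosen
#' configuration is recorded in the returned metadata.
#'
#' @param stages register length (default 4).
#' @param v_peak velocity magnitude deg/s (default 1.78).
#' @param state_duration s per state (default 0.25).
#' @param n_cycles concatenated cycles (default 13).
#' @param sample_rate Hz (default 1000).
#' @param feedback_taps,initial_state,mapping optional explicit shift-register
#'   configuration; defaults trigger the canonical search described above.
#' @return an object of class `tilt_stimulus`: list with `velocity_states`
#'   (deg/s), `state_duration`, `v_peak`, `tilt_cycle` (deg), `n_cycles`,
#'   `tilt_full` (deg), `sample_rate`, `cycle_duration` (s), and `metadata`
#'   (taps, initial state, mapping, cumulative range, peak-to-peak).
#' @examples
#' stim <- prts_stimulus()
#' length(stim$velocity_states)                       # 80
#' diff(range(stim$tilt_cycle))                       # ~4 deg
#' length(stim$tilt_full) / stim$sample_rate          # 260 s
#' @export
prts_stimulus <- function(stages = 4L, v_peak = 1.78, state_duration = 0.25,
                          n_cycles = 13L, sample_rate = 1000,
                          feedback_taps = NULL, initial_state = NULL,
                          mapping = c("0" = 0, "1" = 1, "2" = -1)) {
  if (is.null(initial_state)) initial_state <- c(rep(0L, stages - 1L), 1L)
  search_used <- is.null(feedback_taps)
  if (search_used) {
    target_range <- 9L  # state units; x 0.445 deg = 4.005 deg ~ published 4 deg
    for (taps in primitive_tap_sets(stages)) {
      seq_try <- generate_ternary_mls(stages, taps, initial_state)
      v <- sequence_to_velocity(seq_try, v_peak = 1, mapping = mapping)
      cs <- c(0, cumsum(v))
      if (max(cs) - min(cs) == target_range) {
        feedback_taps <- taps
        break
      }
    }
    if (is.null(feedback_taps))
      stop("no primitive tap set with cumulative range 9 found")
  }
  seq <- generate_ternary_mls(stages, feedback_taps, initial_state)
  velocity_states <- sequence_to_velocity(seq, v_peak = v_peak, mapping = mapping)
  tilt_cycle <- integrate_tilt(velocity_states, state_duration, sample_rate)
  tilt_full <- concatenate_cycles(tilt_cycle, n_cycles)
  cs <- c(0, cumsum(sequence_to_velocity(seq, v_peak = 1, mapping = mapping)))
  structure(
    list(velocity_states = velocity_states,
         state_duration = state_duration,
         v_peak = v_peak,
         tilt_cycle = tilt_cycle,
         n_cycles = as.integer(n_cycles),
         tilt_full = tilt_full,
         sample_rate = sample_rate,
         cycle_duration = length(velocity_states) * state_duration,
         metadata = list(
           stages = as.integer(stages),
           feedback_taps = as.integer(feedback_taps),
           initial_state = as.integer(initial_state),
           mapping = mapping,
           cumulative_range_states = max(cs) - min(cs),
           peak_to_peak_deg = (max(cs) - min(cs)) * v_peak * state_duration,
           amplitude_set_by = if (search_used) "sequence_search" else "explicit_taps")),
    class = "tilt_stimulus")
}

#' @export
print.tilt_stimulus <- function(x, ...) {
  cat(sprintf(
    "PRTS tilt stimulus: %d states x %.2g s at +/-%.3g deg/s\n  cycle %.4g s, %d cycles (%.4g s), peak-to-peak %.4g deg\n  taps (%s), init (%s)\n",
    length(x$velocity_states), x$state_duration, x$v_peak, x$cycle_duration,
    x$n_cycles, x$n_cycles * x$cycle_duration,
    x$metadata$peak_to_peak_deg,
    paste(x$metadata$feedback_taps, collapse = ","),
    paste(x$metadata$initial_state, collapse = ",")))
  invisible(x)
}
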