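#' Butterworth low-pass filter design (bilinear transform)
#'
#' Digital Butterworth low-pass coefficients for [lowpass()]. Analog
#' prototype poles are pre-warped and mapped with the bilinear transform;
#' zeros sit at z = -1.
#'
#' @param order filter order (>= 1).
#' @param cutoff -3 dB cutoff in Hz; must be below the Nyquist frequency.
#' @param sample_rate sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` coefficients
#'   (`a[1] = 1`).
#' @keywords internal
butter_lowpass <- function(order, cutoff, sample_rate) {
  if (order < 1) stop("`order` must be >= 1")
  if (cutoff <= 0 || cutoff >= sample_rate / 2)
    stop(sprintf("`cutoff` (%g Hz) must lie in (0, Nyquist = %g Hz)",
                 cutoff, sample_rate / 2))
  fs2 <- 2 * sample_rate
  warped <- fs2 * tan(pi * cutoff / sample_rate)
  k <- seq_len(order)
  p_analog <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  gain <- warped^order
  p_z <- (fs2 + p_analog) / (fs2 - p_analog)
  gain_z <- Re(gain / prod(fs2 - p_analog))
  poly_from_roots <- function(r) {
    coef <- 1 + 0i
    for (root in r) coef <- c(coef, 0) - c(0, coef * root)
    coef
  }
  a <- Re(poly_from_roots(p_z))
  b <- gain_z * Re(poly_from_roots(rep(-1 + 0i, order)))
  list(b = b, a = a)
}

# steady-state filter state for a unit-step input (direct form II transposed);
# makes forward-backward filtering insensitive to edge transients
lfilter_zi <- function(b, a) {
  m <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, m + 1L - length(b)))
  a <- c(a, rep(0, m + 1L - length(a)))
  b <- b / a[1]; a <- a / a[1]
  companion_t <- rbind(-a[-1], cbind(diag(1, m - 1L), rep(0, m - 1L)))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(m) - t(companion_t), B)
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Applies a Butterworth low-pass filter forward and backward (zero-phase),
#' so the output has no group delay and sway-path sums are not inflated by
#' phase distortion. The effective magnitude response is the squared
#' Butterworth response, i.e. the effective order is `2 * order`. Edges are
#' handled with odd-reflection padding and steady-state initial conditions.
#'
#' @param trace numeric series.
#' @param order Butterworth order of each pass (default 2).
#' @param cutoff -3 dB cutoff of each pass in Hz (default 5).
#' @param sample_rate sampling rate in Hz.
#' @return filtered numeric series, same length as `trace`.
#' @export
lowpass <- function(trace, order = 2, cutoff = 5, sample_rate = 1000) {
  coef <- butter_lowpass(order, cutoff, sample_rate)
  b <- coef$b; a <- coef$a
  n <- length(trace)
  padlen <- min(3L * (max(length(a), length(b)) - 1L) * 10L, n - 1L)
  if (n <= 2L) return(trace)
  zi <- lfilter_zi(b, a)
  ext <- c(2 * trace[1] - trace[(padlen + 1L):2],
           trace,
           2 * trace[n] - trace[(n - 1L):(n - padlen)])
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Mean sway velocity of a spontaneous-sway trace
#'
#' The anterior-posterior sway path is the sum of absolute sample-to-sample
#' differences of the centre-of-mass angle over the analysis window; dividing
#' by the window duration gives the average sway velocity `s`. The first
#' `discard` seconds are dropped (transients); the analysis window is the
#' half-open interval `[discard, discard + window)` in seconds.
#'
#' @param trace numeric COM-angle series (deg).
#' @param sample_rate Hz.
#' @param discard seconds discarded at the start (default 15).
#' @param window analysis window length in seconds (default 30).
#' @return object of class `spontaneous_sway_result`: list with
#'   `sway_velocity_s` (deg/s), `window_start`, `window_length` (s).
#' @export
sway_velocity <- function(trace, sample_rate, discard = 15, window = 30) {
  n_need <- (discard + window) * sample_rate
  if (length(trace) < n_need)
    stop(sprintf("trace has %d samples; need >= %g for discard %g s + window %g s at %g Hz",
                 length(trace), n_need, discard, window, sample_rate))
  idx <- (round(discard * sample_rate) + 1L):round((discard + window) * sample_rate)
  s <- sum(abs(diff(trace[idx]))) / window
  structure(list(sway_velocity_s = s, window_start = discard,
                 window_length = window),
            class = "spontaneous_sway_result")
}

#' Periodic and random sway components of a tilt-trial trace
#'
#' Reshapes the centre-of-mass angle trace of a pseudo-random tilt trial into
#' its stimulus cycles, discards the first `discard_first` cycles (stimulus
#' onset transients), mean-centres each retained cycle, and computes the
#' pointwise arithmetic mean across cycles (the periodic component: the part
#' of sway evoked by the repeated stimulus) and the pointwise standard
#' deviation across cycles (the random component: sway not evoked by the
#' stimulus). Sway power of each component is the sum of its squared trace.
#'
#' @param trace numeric COM-angle series (deg); length must equal
#'   `n_cycles * cycle_duration * sample_rate` exactly.
#' @param cycle_duration s per stimulus cycle (default 20).
#' @param n_cycles number of cycles in the trace (default 13).
#' @param sample_rate Hz.
#' @param discard_first cycles dropped at the start (default 1).
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return object of class `tilt_response_result`: list with `periodic`
#'   (deg, one cycle), `random_sd` (deg, one cycle), `periodic_power`,
#'   `random_power` (deg^2 * samples), `n_cycles_used`.
#' @export
cycle_decompose <- function(trace, cycle_duration = 20, n_cycles = 13,
                            sample_rate = 1000, discard_first = 1,
                            sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  spc <- round(cycle_duration * sample_rate)
  if (length(trace) != spc * n_cycles)
    stop(sprintf("trace length %d != n_cycles (%d) x cycle samples (%d)",
                 length(trace), n_cycles, spc))
  n_used <- as.integer(n_cycles - discard_first)
  if (n_used < 2L)
    stop("need at least 2 retained cycles (n_cycles - discard_first >= 2)")
  cycles <- matrix(trace, nrow = spc, ncol = n_cycles)
  if (discard_first > 0L) cycles <- cycles[, -seq_len(discard_first), drop = FALSE]
  cycles <- sweep(cycles, 2L, colMeans(cycles))   # centre each cycle
  periodic <- rowMeans(cycles)
  dev2 <- rowSums((cycles - periodic)^2)
  denom <- if (sd_denominator == "n-1") n_used - 1L else n_used
  random_sd <- sqrt(dev2 / denom)
  structure(
    list(periodic = periodic, random_sd = random_sd,
         periodic_power = sway_power(periodic),
         random_power = sway_power(random_sd),
         n_cycles_used = n_used),
    class = "tilt_response_result")
}

#' Sway power of a component trace
#'
#' Sum of the squared samples; no normalisation by trace length, so units
#' are deg^2 * samples.
#'
#' @param component numeric trace (deg).
#' @return scalar power.
#' @export
sway_power <- function(component) {
  if (length(component) == 0L) stop("empty trace")
  sum(component^2)
}
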