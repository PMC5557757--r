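#' Bateman (bi-exponential) phasic SCR kernel
#'
#' The canonical rise-decay shape used to model a single phasic skin
#' conductance response:
#' \deqn{k(t) = (e^{-t/\tau_d} - e^{-t/\tau_r}) / c, \quad t \ge 0}
#' with rise constant \eqn{\tau_r} < decay constant \eqn{\tau_d}, and `c`
#' chosen so the kernel's analytic maximum is exactly 1. With a unit-peak
#' kernel, an injected event of amplitude A produces a phasic excursion whose
#' maximum is exactly A.
#'
#' @param t time since kernel onset, seconds (values < 0 give 0).
#' @param tau_rise,tau_decay rise and decay time constants, seconds.
#' @return Kernel values in `[0, 1]`.
#' @export
scr_kernel <- function(t, tau_rise = 0.75, tau_decay = 4) {
  stopifnot(tau_rise > 0, tau_decay > tau_rise)
  peak <- scr_kernel_peak_time(tau_rise, tau_decay)
  c0 <- exp(-peak / tau_decay) - exp(-peak / tau_rise)
  out <- (exp(-t / tau_decay) - exp(-t / tau_rise)) / c0
  out[t < 0] <- 0
  out
}

#' Analytic peak time of the Bateman kernel
#'
#' @inheritParams scr_kernel
#' @return Seconds after kernel onset at which the kernel attains its maximum:
#'   \eqn{t^* = \tau_r \tau_d \log(\tau_d/\tau_r) / (\tau_d - \tau_r)}.
#' @export
scr_kernel_peak_time <- function(tau_rise = 0.75, tau_decay = 4) {
  tau_rise * tau_decay * log(tau_decay / tau_rise) / (tau_decay - tau_rise)
}

#' Build a skin conductance trace container
#'
#' @param time numeric vector of sample times, strictly increasing, seconds.
#' @param conductance numeric vector of conductance values, microsiemens.
#' @param sampling_rate sampling rate in Hz.
#' @return Object of class `"sc_trace"` (a list with `time`, `conductance`,
#'   `sampling_rate`).
#' @export
sc_trace <- function(time, conductance, sampling_rate) {
  if (length(time) < 2) stop("a trace needs at least 2 samples")
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing")
  if (!all(is.finite(conductance))) stop("`conductance` must be finite")
  if (length(time) != length(conductance)) stop("time/conductance length mismatch")
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive")
  structure(
    list(time = as.double(time), conductance = as.double(conductance),
         sampling_rate = as.double(sampling_rate)),
    class = "sc_trace"
  )
}

#' @export
print.sc_trace <- function(x, ...) {
  cat(sprintf(
    "Skin conductance trace: %d samples at %g Hz (%.1f s), %.3f-%.3f uS\n",
    length(x$time), x$sampling_rate, diff(range(x$time)),
    min(x$conductance), max(x$conductance)
  ))
  invisible(x)
}

#' @export
as.data.frame.sc_trace <- function(x, ...) {
  data.frame(time_s = x$time, conductance_uS = x$conductance)
}

#' Simulate a skin conductance trace with event-related phasic responses
#'
#' The trace is the sum of a tonic level, a slow linear drift, one unit-peak
#' Bateman-kernel phasic component per stimulation event scaled by its
#' amplitude, and white measurement noise. The kernel onset is delayed
#' relative to the stimulus onset so that, at the default settings, the
#' post-offset peak latency averages `target_peak_latency_s` (4.593 s); an
#' optional per-event Gaussian jitter on that delay spreads latencies across
#' events.
#'
#' @param events data frame with columns `onset_s`, `offset_s` (seconds);
#'   events must not overlap.
#' @param amplitudes nonnegative phasic amplitude (microsiemens) per event.
#' @param tonic_level tonic skin conductance level, microsiemens.
#' @param duration_s total trace duration; default covers the last event's
#'   measurement window plus 15 s.
#' @param sampling_rate Hz.
#' @param noise_sd white noise SD, microsiemens.
#' @param drift_slope linear drift, microsiemens per second.
#' @param tau_rise,tau_decay Bateman kernel time constants, seconds.
#' @param target_peak_latency_s mean peak latency after stimulus offset that
#'   the kernel onset delay is calibrated to.
#' @param latency_jitter_sd SD (seconds) of per-event jitter on the kernel
#'   onset delay; 0 gives deterministic latencies.
#' @return An [sc_trace()].
#' @examples
#' ev <- data.frame(onset_s = 10, offset_s = 11)
#' tr <- simulate_sc_trace(ev, amplitudes = 1, tonic_level = 5,
#'                         noise_sd = 0, latency_jitter_sd = 0)
#' max(tr$conductance) - 5 # ~1 uS
#' @export
simulate_sc_trace <- function(events, amplitudes, tonic_level,
                              duration_s = NULL, sampling_rate = 20,
                              noise_sd = 0.02, drift_slope = 0,
                              tau_rise = 0.75, tau_decay = 4,
                              target_peak_latency_s = 4.593,
                              latency_jitter_sd = 1.5) {
  stopifnot(is.data.frame(events), all(c("onset_s", "offset_s") %in% names(events)))
  n_ev <- nrow(events)
  stopifnot(length(amplitudes) == n_ev, sampling_rate > 0, noise_sd >= 0)
  if (any(amplitudes < 0)) stop("phasic amplitudes must be nonnegative")
  if (n_ev > 0) {
    if (any(events$offset_s <= events$onset_s)) stop("event offset must follow onset")
    ord <- order(events$onset_s)
    if (any(events$onset_s[ord][-1] < events$offset_s[ord][-n_ev])) {
      stop("stimulation events must not overlap")
    }
  }
  if (is.null(duration_s)) {
    duration_s <- if (n_ev > 0) max(events$offset_s) + 15 else 60
  }

  time <- seq(0, duration_s, by = 1 / sampling_rate)
  g <- rep(tonic_level, length(time)) + drift_slope * time

  t_peak <- scr_kernel_peak_time(tau_rise, tau_decay)
  for (i in seq_len(n_ev)) {
    stim_dur <- events$offset_s[i] - events$onset_s[i]
    # kernel onset delay after stimulus onset, calibrated so the kernel peak
    # falls target_peak_latency_s after the stimulus offset
    delay <- target_peak_latency_s + stim_dur - t_peak
    if (latency_jitter_sd > 0) {
      delay <- delay + stats::rnorm(1, 0, latency_jitter_sd)
    }
    delay <- max(delay, 0.1)
    onset <- events$onset_s[i] + delay
    g <- g + amplitudes[i] * scr_kernel(time - onset, tau_rise, tau_decay)
  }
  if (noise_sd > 0) g <- g + stats::rnorm(length(time), 0, noise_sd)
  sc_trace(time, g, sampling_rate)
}

#' Write / read a trace as two-column CSV
#'
#' Schema: `time_s, conductance_uS` with a header line.
#'
#' @param trace an [sc_trace()].
#' @param path file path.
#' @return `read_trace_csv` returns an [sc_trace()]; `write_trace_csv`
#'   invisibly returns `path`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sc_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "conductance_uS") %in% names(df)))
  dt <- diff(df$time_s)
  sc_trace(df$time_s, df$conductance_uS, sampling_rate = 1 / stats::median(dt))
}
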