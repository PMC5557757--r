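#' Conductance value immediately before a stimulus onset
#'
#' The pre-stimulus baseline for the event-related SCR is the conductance at
#' the last sample strictly before the stimulus onset (a point value, not a
#' pre-window mean).
#'
#' @param trace an [sc_trace()].
#' @param onset_s stimulus onset time, seconds.
#' @return Conductance (microsiemens) at the last sample with
#'   `time < onset_s`.
#' @export
pre_stimulus_value <- function(trace, onset_s) {
  stopifnot(inherits(trace, "sc_trace"))
  i <- findInterval(onset_s, trace$time, left.open = TRUE)
  if (i < 1) {
    stop("stimulus onset at ", onset_s,
         " s precedes the first trace sample (", trace$time[1], " s)")
  }
  # findInterval with left.open gives the last index with time < onset
  trace$conductance[i]
}

#' Extract the event-related SCR for one stimulation
#'
#' The event-related SCR is defined as the peak (maximum conductance) within
#' `window_s` seconds after the stimulus offset, minus the conductance
#' immediately before the stimulus onset. The search window is the half-open
#' interval `(offset, offset + window_s]`; a response is counted
#' (`responded = TRUE`) when the amplitude delta reaches the minimum
#' amplitude criterion. Windows overlapping a following event are not
#' truncated.
#'
#' @param trace an [sc_trace()].
#' @param event one-row data frame (or list) with `onset_s` and `offset_s`.
#' @param window_s post-offset search window, seconds (default 10).
#' @param amplitude_criterion_uS minimum delta (microsiemens) for a trial to
#'   count as showing an event-related SCR; 0.05 is the conventional
#'   electrodermal minimum response.
#' @return A one-row data frame: `pre_stimulus_uS`, `peak_uS`,
#'   `peak_latency_s` (after offset), `delta_uS`, `responded`.
#' @examples
#' ev <- data.frame(onset_s = 5, offset_s = 6)
#' tr <- simulate_sc_trace(ev, 1.2, tonic_level = 5, noise_sd = 0,
#'                         latency_jitter_sd = 0)
#' extract_event_scr(tr, ev)
#' @export
extract_event_scr <- function(trace, event, window_s = 10,
                              amplitude_criterion_uS = 0.05) {
  stopifnot(inherits(trace, "sc_trace"), window_s > 0)
  onset <- event$onset_s[1]
  offset <- event$offset_s[1]
  if (offset <= onset) stop("event offset must follow onset")
  pre <- pre_stimulus_value(trace, onset)
  in_window <- trace$time > offset & trace$time <= offset + window_s
  if (!any(in_window)) {
    stop("trace does not cover the window (", offset, ", ", offset + window_s,
         "] after the stimulus offset")
  }
  if (max(trace$time) < offset + window_s) {
    stop("trace ends at ", max(trace$time), " s, before the ", window_s,
         " s post-offset window is complete")
  }
  idx <- which(in_window)
  k <- idx[which.max(trace$conductance[idx])]
  peak <- trace$conductance[k]
  delta <- peak - pre
  data.frame(
    pre_stimulus_uS = pre,
    peak_uS = peak,
    peak_latency_s = trace$time[k] - offset,
    delta_uS = delta,
    responded = delta >= amplitude_criterion_uS
  )
}

#' Extract event-related SCRs for all events of a session
#'
#' @param trace an [sc_trace()].
#' @param events data frame with `onset_s`, `offset_s`, `intensity` and
#'   optionally `trial_index`.
#' @inheritParams extract_event_scr
#' @return Data frame with one row per event (input columns plus the
#'   [extract_event_scr()] fields).
#' @export
extract_session_scr <- function(trace, events, window_s = 10,
                                amplitude_criterion_uS = 0.05) {
  out <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    extract_event_scr(trace, events[i, ], window_s, amplitude_criterion_uS)
  }))
  cbind(events, out, row.names = NULL)
}

#' Participant inclusion rule for the SCR analysis
#'
#' A participant enters the event-related SCR analysis only if they showed an
#' event-related SCR (a responded trial) for the weak and for the strong
#' intensity in at least one trial each.
#'
#' @param responded logical vector of per-trial response flags.
#' @param intensity character vector (`"weak"`/`"strong"`) parallel to
#'   `responded`.
#' @return `TRUE` iff at least one responded weak trial and at least one
#'   responded strong trial exist.
#' @export
participant_inclusion <- function(responded, intensity) {
  stopifnot(length(responded) == length(intensity))
  if (!all(c("weak", "strong") %in% intensity)) {
    stop("trials for both intensities (weak and strong) are required")
  }
  any(responded[intensity == "weak"]) && any(responded[intensity == "strong"])
}

#' Per-participant summary of event-related SCRs
#'
#' Arithmetic means of the amplitude delta and of the pre-stimulus baseline,
#' separately per stimulus intensity, plus the inclusion flag.
#'
#' @param event_scrs data frame as returned by [extract_session_scr()] (needs
#'   `intensity`, `delta_uS`, `pre_stimulus_uS`, `responded`).
#' @param participant_id optional id copied into the output.
#' @return One-row data frame: `mean_delta_weak/strong`,
#'   `mean_baseline_weak/strong`, `n_responded_weak/strong`, `included`.
#' @export
summarize_scr <- function(event_scrs, participant_id = NA_character_) {
  for (lev in c("weak", "strong")) {
    if (!any(event_scrs$intensity == lev)) {
      stop("no trials with intensity '", lev, "' for participant ",
           participant_id)
    }
  }
  m <- function(col, lev) mean(event_scrs[[col]][event_scrs$intensity == lev])
  data.frame(
    participant_id = participant_id,
    mean_delta_weak = m("delta_uS", "weak"),
    mean_delta_strong = m("delta_uS", "strong"),
    mean_baseline_weak = m("pre_stimulus_uS", "weak"),
    mean_baseline_strong = m("pre_stimulus_uS", "strong"),
    n_responded_weak = sum(event_scrs$responded[event_scrs$intensity == "weak"]),
    n_responded_strong = sum(event_scrs$responded[event_scrs$intensity == "strong"]),
    included = participant_inclusion(event_scrs$responded, event_scrs$intensity)
  )
}
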