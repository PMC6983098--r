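# Breath (BPM) and pulse (PPM) event estimators, and the piecewise-constant
# interpolator that turns event streams into uniformly sampled derived
# signals.
#
# Both estimators treat the band-limited input as approximately sine-shaped
# and track alternating minima and maxima with a hysteresis threshold, so a
# cycle is only committed once the signal has retraced a fraction of the
# running peak-to-trough excursion. A refractory period (a fraction of the
# band's shortest admissible cycle) suppresses double detections.

#' Construct an event stream
#'
#' @param times Event timestamps in seconds, strictly increasing.
#' @param rate Events per minute at each event.
#' @param amplitude Optional per-cycle max-minus-min excursion (present for
#'   breath streams, absent for pulse streams).
#' @return Object of class `event_stream`.
#' @export
event_stream <- function(times, rate, amplitude = NULL) {
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  stopifnot(length(rate) == length(times),
            is.null(amplitude) || length(amplitude) == length(times))
  structure(list(times = as.numeric(times), rate = as.numeric(rate),
                 amplitude = if (!is.null(amplitude)) as.numeric(amplitude)),
            class = "event_stream")
}

#' @rdname event_stream
#' @param e An object to test / an `event_stream`.
#' @export
is_empty_stream <- function(e) {
  inherits(e, "event_stream") && length(e$times) == 0L
}

# Alternating min/max tracker. Confirms an extremum once the signal retraces
# more than `hyst_frac` of the running excursion; peaks closer than
# `refractory_s` to the previous one are merged (the higher wins).
detect_cycles <- function(x, fs, f_max, hyst_frac = 0.2, refractory_frac = 0.4) {
  n <- length(x)
  exc <- diff(range(x))
  if (!is.finite(exc) || exc <= 0) {
    return(list(peak_i = integer(0), amp = numeric(0)))
  }
  refractory <- refractory_frac / f_max * fs   # samples
  h <- hyst_frac * exc
  peak_i <- integer(0)
  amp <- numeric(0)
  seeking_max <- TRUE
  cur_max <- x[1]; cur_max_i <- 1L
  cur_min <- x[1]
  cyc_min <- x[1]                              # min since previous peak
  for (i in 2:n) {
    v <- x[i]
    if (seeking_max) {
      if (v > cur_max) { cur_max <- v; cur_max_i <- i }
      cyc_min <- min(cyc_min, v)
      if (cur_max - v > h) {
        np <- length(peak_i)
        if (np > 0 && (cur_max_i - peak_i[np]) < refractory) {
          if (cur_max > x[peak_i[np]]) {       # replace spurious double peak
            peak_i[np] <- cur_max_i
            amp[np] <- max(amp[np], cur_max - cyc_min)
          }
        } else {
          peak_i <- c(peak_i, cur_max_i)
          amp <- c(amp, cur_max - cyc_min)
        }
        exc <- 0.8 * exc + 0.2 * (cur_max - cyc_min)
        h <- hyst_frac * exc
        seeking_max <- FALSE
        cur_min <- v
        cyc_min <- v
      }
    } else {
      if (v < cur_min) cur_min <- v
      cyc_min <- min(cyc_min, v)
      if (v - cur_min > h) {
        seeking_max <- TRUE
        cur_max <- v; cur_max_i <- i
      }
    }
  }
  list(peak_i = peak_i, amp = amp)
}

rate_stream_from_peaks <- function(det, fs, with_amplitude) {
  if (length(det$peak_i) < 2L) {
    return(event_stream(numeric(0), numeric(0),
                        if (with_amplitude) numeric(0)))
  }
  times <- (det$peak_i - 1) / fs
  rate <- 60 / diff(times)
  rate <- c(rate[1], rate)                     # first event holds next rate
  event_stream(times, rate, if (with_amplitude) det$amp)
}

#' Estimate breath events from a respiration-band signal
#'
#' One event per detected breath cycle; the per-event rate is 60 over the
#' preceding inter-peak interval (breaths per minute) and the amplitude is
#' the cycle's max-minus-min excursion. An input with no detectable cycles
#' (for example a constant series) yields an empty stream, not an error.
#'
#' @param x Numeric series band-limited to roughly 0.1--0.5 Hz.
#' @param fs Sampling rate of `x` in Hz.
#' @return An [event_stream()] with amplitudes.
#' @export
estimate_breath_events <- function(x, fs) {
  rate_stream_from_peaks(detect_cycles(x, fs, f_max = 0.5), fs,
                         with_amplitude = TRUE)
}

#' Estimate pulse events from a cardiac-band signal
#'
#' As [estimate_breath_events()] but for the 0.8--2.9 Hz cardiac band and
#' without an amplitude field; the per-event rate is in pulsations per
#' minute.
#'
#' @inheritParams estimate_breath_events
#' @return An [event_stream()] without amplitudes.
#' @export
estimate_pulse_events <- function(x, fs) {
  rate_stream_from_peaks(detect_cycles(x, fs, f_max = 2.9), fs,
                         with_amplitude = FALSE)
}

#' Piecewise-constant interpolation of an event stream
#'
#' Samples the stream's rate (or amplitude) field on a uniform 50 Hz grid by
#' holding the last known value: the value at time t is the field value of
#' the most recent event at or before t, and the first event's value before
#' that.
#'
#' @param e A nonempty [event_stream()].
#' @param field `"rate"` or `"amplitude"`.
#' @param fs_out Output sampling rate in Hz (50 in the deployed chain).
#' @param t_start,t_end Time span to sample, in seconds; defaults to
#'   `[0, last event time]`.
#' @return Object of class `derived_signal`: list with `name` (field),
#'   `fs_out`, `t_start` and the numeric vector `values`.
#' @export
interpolate_events <- function(e, field = c("rate", "amplitude"),
                               fs_out = 50, t_start = 0, t_end = NULL) {
  field <- match.arg(field)
  if (is_empty_stream(e)) {
    stop("cannot interpolate an empty event stream (no signal detected)",
         call. = FALSE)
  }
  vals <- if (field == "rate") e$rate else e$amplitude
  if (is.null(vals)) {
    stop("event stream has no '", field, "' field", call. = FALSE)
  }
  if (is.null(t_end)) t_end <- max(e$times) + 1 / fs_out
  n_out <- round((t_end - t_start) * fs_out)
  tt <- t_start + (seq_len(n_out) - 1) / fs_out
  idx <- findInterval(tt, e$times)
  idx[idx == 0L] <- 1L                         # hold first value before t1
  structure(list(name = field, fs_out = fs_out, t_start = t_start,
                 values = vals[idx]),
            class = "derived_signal")
}
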