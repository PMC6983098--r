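# Recording container and the end-to-end feature-extraction chain:
# filters -> breath/pulse event estimators -> 50 Hz piecewise-constant
# rate/amplitude streams -> 14 window statistics -> 84 named features per
# 10-s emission.

#' Construct a biosignal recording
#'
#' @param channel `"ECG"` or `"TEB"`.
#' @param fs Sampling rate in Hz (250 for ECG, 100 for TEB in the study
#'   set-up; any positive rate is accepted).
#' @param samples Numeric time series, all finite.
#' @param subject_id Subject identifier.
#' @param labels Optional data frame with columns `start_s`, `end_s`,
#'   `class` (values in `"neutral"`, `"sadness"`, `"disgust"`) annotating
#'   non-overlapping intervals.
#' @return Object of class `recording`.
#' @export
recording <- function(channel = c("ECG", "TEB"), fs, samples,
                      subject_id = "S1", labels = NULL) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(fs), fs > 0, all(is.finite(samples)))
  if (!is.null(labels)) {
    stopifnot(all(c("start_s", "end_s", "class") %in% names(labels)))
    if (nrow(labels) > 1) {
      o <- order(labels$start_s)
      if (any(labels$start_s[o][-1] < labels$end_s[o][-nrow(labels)])) {
        stop("label intervals overlap", call. = FALSE)
      }
    }
  }
  structure(list(channel = channel, fs = fs, samples = as.numeric(samples),
                 subject_id = subject_id, labels = labels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s channel, fs = %g Hz, %.1f s, subject %s\n",
              x$channel, x$fs, length(x$samples) / x$fs, x$subject_id))
  invisible(x)
}

# The six derived 50 Hz streams feeding the statistics block. Per
# measurement: PPM = cardiac rate, RT = respiration rate, RD = respiration
# depth (cycle amplitude). "E_" prefixes the ECG measurement.
derived_signal_names <- function() {
  c("E_PPM", "E_RT", "E_RD", "TEB_PPM", "TEB_RT", "TEB_RD")
}

#' Canonical names of the 84 features
#'
#' The cross product of the six derived signals (`E_PPM`, `E_RT`, `E_RD`,
#' `TEB_PPM`, `TEB_RT`, `TEB_RD`) and the 14 window statistics
#' ([statistic_names()]), joined with underscores: 42 features per
#' measurement, 84 in total.
#'
#' @return Character vector of length 84.
#' @export
feature_names <- function() {
  as.vector(t(outer(derived_signal_names(), statistic_names(), paste,
                    sep = "_")))
}

#' Alias map between feature-name dialects
#'
#' The canonical names use the `E_`/`TEB_` signal prefixes; an alternative
#' dialect spells the ECG prefixes `ECG_` and calls the TEB cardiac stream
#' `TEB_BPM`. This map translates the alternative prefixes to the canonical
#' ones.
#'
#' @return Named character vector: `alias prefix -> canonical prefix`.
#' @export
feature_alias_map <- function() {
  c(ECG_PPM = "E_PPM", ECG_RT = "E_RT", ECG_RD = "E_RD",
    TEB_BPM = "TEB_PPM", TEB_RT = "TEB_RT", TEB_RD = "TEB_RD")
}

#' Canonicalize feature names given in the alias dialect
#' @param names Character vector of feature names in either dialect.
#' @return Character vector of canonical names.
#' @export
canonical_feature_names <- function(names) {
  map <- feature_alias_map()
  for (a in names(map)) {
    names <- sub(paste0("^", a, "_"), paste0(map[[a]], "_"), names)
  }
  names
}

# Run one measurement channel through its filter chain and event
# estimators; returns the three derived 50 Hz streams (or NULL where no
# events were detected).
channel_streams <- function(rec, t_end) {
  fs <- rec$fs
  x <- rec$samples
  if (rec$channel == "ECG") {
    cardiac <- apply_filter(design_filter("MFECG", fs), x)
    lf <- apply_filter(design_filter("LFECG", fs), x)
    resp <- apply_filter(design_filter("RFECG", fs), lf)
    prefix <- "E"
  } else {
    lf <- apply_filter(design_filter("LFTEB", fs), x)
    resp <- apply_filter(design_filter("RFTEB", fs), lf)
    cardiac <- apply_filter(design_filter("EFTEB", fs), lf)
    prefix <- "TEB"
  }
  pulse <- estimate_pulse_events(cardiac, fs)
  breath <- estimate_breath_events(resp, fs)
  interp_or_null <- function(e, field) {
    if (is_empty_stream(e)) NULL
    else interpolate_events(e, field, fs_out = 50, t_start = 0, t_end = t_end)
  }
  out <- list(interp_or_null(pulse, "rate"),
              interp_or_null(breath, "rate"),
              interp_or_null(breath, "amplitude"))
  names(out) <- paste(prefix, c("PPM", "RT", "RD"), sep = "_")
  out
}

#' Extract the 84-feature frames from an ECG/TEB recording pair
#'
#' Runs both channels through the full chain and computes the 14 statistics
#' of each of the six derived streams over a sliding window, emitting one
#' frame per emission period after the first full window. Streams in which
#' no cardiac or respiratory cycles could be detected (degenerate input)
#' yield `NA` features and are listed in the `empty_streams` attribute of
#' the result; they never abort extraction.
#'
#' @param ecg,teb [recording()] objects for the two channels; they must
#'   share a common time span of at least one window.
#' @param window_s Statistics window length in seconds (default 60, i.e.
#'   3000 samples at the 50 Hz derived rate).
#' @param step_s Emission period in seconds (default 10).
#' @return Data frame with one row per emission: `emission_time`,
#'   `subject_id`, `label`, then the 84 canonical features.
#' @export
extract_features <- function(ecg, teb, window_s = 60, step_s = 10) {
  stopifnot(inherits(ecg, "recording"), inherits(teb, "recording"))
  if (ecg$channel != "ECG" || teb$channel != "TEB") {
    stop("arguments must be an ECG recording and a TEB recording",
         call. = FALSE)
  }
  t_end <- min(length(ecg$samples) / ecg$fs, length(teb$samples) / teb$fs)
  if (t_end < window_s) {
    stop(sprintf("common time span (%.1f s) shorter than one window (%g s)",
                 t_end, window_s), call. = FALSE)
  }
  streams <- c(channel_streams(ecg, t_end), channel_streams(teb, t_end))
  streams <- streams[derived_signal_names()]
  names(streams) <- derived_signal_names()
  empty <- names(streams)[vapply(streams, is.null, logical(1))]

  emissions <- seq(window_s, t_end, by = step_s)
  fs_out <- 50
  feats <- matrix(NA_real_, nrow = length(emissions),
                  ncol = length(feature_names()),
                  dimnames = list(NULL, feature_names()))
  for (k in seq_along(emissions)) {
    te <- emissions[k]
    i0 <- round((te - window_s) * fs_out) + 1
    i1 <- round(te * fs_out)
    for (sn in setdiff(names(streams), empty)) {
      v <- streams[[sn]]$values
      i1s <- min(i1, length(v))
      st <- compute_statistics(v[i0:i1s])
      feats[k, paste(sn, names(st), sep = "_")] <- st
    }
  }
  lab <- rep(NA_character_, length(emissions))
  if (!is.null(ecg$labels)) {
    for (j in seq_len(nrow(ecg$labels))) {
      in_iv <- emissions > ecg$labels$start_s[j] &
               emissions <= ecg$labels$end_s[j]
      lab[in_iv] <- ecg$labels$class[j]
    }
  }
  out <- data.frame(emission_time = emissions,
                    subject_id = ecg$subject_id,
                    label = lab,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(feats))
  attr(out, "empty_streams") <- empty
  out
}
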