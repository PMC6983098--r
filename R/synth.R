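# Synthetic data emulating the study material on both levels:
#  * raw ECG/TEB-like recordings whose cardiac and respiratory rate and
#    amplitude shift with the emotion class, to exercise the signal chain;
#  * tabular labeled feature datasets with per-subject random effects, the
#    statistical structure that makes subject-wise generalization hard and
#    that the nested-fold fitness is designed to cope with.
# Neither is calibrated to the original recordings; effect sizes are free
# parameters documented in the methods vignette.

#' Subject profile for signal synthesis
#'
#' @param base_heart_rate Resting heart rate, beats/min (within the
#'   0.8--2.9 Hz cardiac band, i.e. 48--174).
#' @param base_breath_rate Resting breath rate, breaths/min (within the
#'   0.1--0.5 Hz band, i.e. 6--30).
#' @param base_breath_amplitude Breathing excursion, arbitrary units.
#' @param subject_effect_sd Std of per-subject random offsets added to the
#'   base rates.
#' @param noise_sd Additive white-noise std on both channels.
#' @param class_effects Named list per class (`neutral`, `sadness`,
#'   `disgust`) of additive shifts: `hr` (beats/min), `br` (breaths/min),
#'   `amp` (amplitude units).
#' @return Object of class `subject_profile`.
#' @export
subject_profile <- function(base_heart_rate = 72, base_breath_rate = 15,
                            base_breath_amplitude = 1,
                            subject_effect_sd = 0, noise_sd = 0.05,
                            class_effects = list(
                              neutral = c(hr = 0,  br = 0,  amp = 0),
                              sadness = c(hr = -6, br = -3, amp = -0.2),
                              disgust = c(hr = 8,  br = 4,  amp = 0.15))) {
  stopifnot(base_heart_rate >= 48, base_heart_rate <= 174,
            base_breath_rate >= 6, base_breath_rate <= 30,
            base_breath_amplitude > 0, noise_sd >= 0)
  structure(list(base_heart_rate = base_heart_rate,
                 base_breath_rate = base_breath_rate,
                 base_breath_amplitude = base_breath_amplitude,
                 subject_effect_sd = subject_effect_sd,
                 noise_sd = noise_sd,
                 class_effects = class_effects),
            class = "subject_profile")
}

# raised-cosine pulse train: one smooth peak per cardiac cycle
pulse_train <- function(t, rate_hz, width = 0.12) {
  phase <- (t * rate_hz) %% 1
  ifelse(phase < width, 0.5 * (1 - cos(2 * pi * phase / width)), 0)
}

#' Synthesize an emotion-modulated ECG/TEB recording pair
#'
#' The ECG channel (250 Hz) is a quasi-periodic raised-cosine pulse train
#' at the class-shifted heart rate plus a respiration-band baseline wander
#' and white noise; the TEB channel (100 Hz) is a respiration sinusoid at
#' the class-shifted rate and amplitude plus a small cardiac-band component
#' and noise. The programmed ground-truth rates are stored in the
#' `ground_truth` attribute for oracle checks.
#'
#' @param p A [subject_profile()].
#' @param emotion `"neutral"`, `"sadness"` or `"disgust"`.
#' @param duration_s Duration in seconds (>= 120 recommended so feature
#'   extraction has at least one full window past the filter transients).
#' @param seed Integer seed (bitwise-reproducible output).
#' @param subject_id Subject identifier stamped on both recordings.
#' @return List with elements `ecg` and `teb` ([recording()] objects).
#' @export
synth_recording <- function(p, emotion, duration_s, seed = 1L,
                            subject_id = "S1") {
  stopifnot(inherits(p, "subject_profile"))
  if (!emotion %in% names(p$class_effects)) {
    stop("unknown emotion class: ", emotion, call. = FALSE)
  }
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  eff <- p$class_effects[[emotion]]
  set.seed(seed)
  hr <- p$base_heart_rate + eff[["hr"]] +
    stats::rnorm(1, 0, p$subject_effect_sd)
  br <- p$base_breath_rate + eff[["br"]] +
    stats::rnorm(1, 0, p$subject_effect_sd / 3)
  amp <- max(0.1, p$base_breath_amplitude + eff[["amp"]])
  hr <- min(174, max(48, hr))
  br <- min(30, max(6, br))

  lab <- data.frame(start_s = 0, end_s = duration_s, class = emotion,
                    stringsAsFactors = FALSE)
  t_ecg <- seq(0, duration_s - 1 / 250, by = 1 / 250)
  ecg <- pulse_train(t_ecg, hr / 60) +
    0.15 * amp * sin(2 * pi * br / 60 * t_ecg) +
    stats::rnorm(length(t_ecg), 0, p$noise_sd)
  t_teb <- seq(0, duration_s - 1 / 100, by = 1 / 100)
  teb <- amp * sin(2 * pi * br / 60 * t_teb) +
    0.2 * sin(2 * pi * hr / 60 * t_teb) +
    stats::rnorm(length(t_teb), 0, p$noise_sd)

  out <- list(
    ecg = recording("ECG", 250, ecg, subject_id, lab),
    teb = recording("TEB", 100, teb, subject_id, lab)
  )
  attr(out, "ground_truth") <- c(heart_rate = hr, breath_rate = br,
                                 breath_amplitude = amp)
  out
}

#' Synthesize a tabular labeled feature dataset with subject effects
#'
#' Informative features carry a class-mean separation (class m's mean is
#' `class_gap * (m - 2)`, i.e. classes spaced `class_gap` apart) on top of
#' a per-subject, per-feature random offset and unit observation noise;
#' uninformative features carry only the subject offset and noise. Classes
#' are exactly balanced within every subject. The subject-effect scale is
#' `subject_sd` on the uninformative features and the (much smaller)
#' `subject_sd_informative` on the informative ones: with `subject_sd`
#' dominating `class_gap`, the uninformative features are pure subject
#' idiosyncrasy, which a wrapper criterion judged on the design set alone
#' will happily exploit -- the pathology the nested-fold fitness targets --
#' while the informative features remain transferable to new subjects.
#'
#' @param S Number of subjects (>= 3).
#' @param n_per_class Patterns per class per subject.
#' @param informative Indices of the informative features.
#' @param class_gap Spacing of adjacent class means on informative
#'   features, in units of the observation noise std.
#' @param subject_sd Std of the per-subject random offsets on the
#'   uninformative features.
#' @param subject_sd_informative Std of the per-subject offsets on the
#'   informative features (individual variability of the true markers).
#' @param L_total Total number of features.
#' @param seed Integer seed.
#' @return A [labeled_dataset()] with 3 classes; the `informative`
#'   attribute records the informative index set.
#' @export
synth_feature_dataset <- function(S = 8, n_per_class = 20,
                                  informative = c(1, 2), class_gap = 1,
                                  subject_sd = 3,
                                  subject_sd_informative = 0.5,
                                  L_total = 20, seed = 1L) {
  stopifnot(S >= 3, n_per_class >= 1, L_total >= 1)
  if (any(informative < 1 | informative > L_total)) {
    stop("informative indices outside [1, L_total]", call. = FALSE)
  }
  set.seed(seed)
  M <- 3L
  n_sub <- M * n_per_class
  N <- S * n_sub
  X <- matrix(0, nrow = N, ncol = L_total,
              dimnames = list(NULL, sprintf("f%02d", seq_len(L_total))))
  y <- integer(N)
  subjects <- character(N)
  row <- 1L
  off_sd <- rep(subject_sd, L_total)
  off_sd[informative] <- subject_sd_informative
  for (s in seq_len(S)) {
    offs <- stats::rnorm(L_total, 0, off_sd)
    for (m in seq_len(M)) {
      idx <- row:(row + n_per_class - 1L)
      mu <- rep(0, L_total)
      mu[informative] <- class_gap * (m - 2)
      X[idx, ] <- matrix(rep(mu + offs, each = n_per_class),
                         nrow = n_per_class) +
        matrix(stats::rnorm(n_per_class * L_total), nrow = n_per_class)
      y[idx] <- m
      subjects[idx] <- sprintf("S%02d", s)
      row <- row + n_per_class
    }
  }
  d <- labeled_dataset(X, y, subjects,
                       classes = c("neutral", "sadness", "disgust"))
  attr(d, "informative") <- informative
  d
}
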