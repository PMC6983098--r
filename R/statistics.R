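# The 14 summary statistics computed over each 60-s window of a derived
# signal. Conventions (fixed here, used identically by the cost model):
#  * trimmed mean 25%: drop the lowest and highest 25% of sorted samples,
#    average the middle half (base `mean(trim = 0.25)`)
#  * percentiles: linear interpolation between order statistics (type 7)
#  * kurtosis: Pearson (non-excess) m4/m2^2, Gaussian reference 3
#  * skewness: standardized third central moment m3/m2^(3/2)
#  * mean absolute deviation: mean(|x - mean(x)|)
#  * baseline: mean of the samples at or below the window's 10th
#    percentile -- a floor-level estimate distinct from the mean
#  * geometric/harmonic mean: defined only for strictly positive windows;
#    on non-positive input those two entries are NA, the rest are computed

#' Names of the 14 window statistics
#' @return Character vector of length 14, in canonical order.
#' @export
statistic_names <- function() {
  c("Trimmean", "Median", "Prc25", "Prc75", "Kurtosis", "Skewness",
    "Std", "Mad", "Geomean", "Harmean", "Baseline", "Max", "Min", "Mean")
}

#' Compute the 14 window statistics
#'
#' @param window Nonempty numeric vector (one analysis window of a derived
#'   signal, typically 3000 samples = 60 s at 50 Hz).
#' @return Named numeric vector of length 14 (names from
#'   [statistic_names()]). `Geomean` and `Harmean` are `NA` when the window
#'   contains non-positive values; all other entries are always finite for
#'   finite input.
#' @examples
#' compute_statistics(rep(3, 100))["Std"]  # 0
#' @export
compute_statistics <- function(window) {
  if (length(window) == 0L || !is.numeric(window)) {
    stop("window must be a nonempty numeric vector", call. = FALSE)
  }
  n <- length(window)
  mu <- mean(window)
  cen <- window - mu
  m2 <- mean(cen^2)
  # degenerate (constant) windows: skewness/kurtosis of a point mass are
  # reported as 0 rather than 0/0
  if (m2 > 0) {
    skw <- e1071::skewness(window, type = 1)
    krt <- e1071::kurtosis(window, type = 1) + 3   # non-excess
  } else {
    skw <- 0
    krt <- 0
  }
  positive <- all(window > 0)
  p10 <- stats::quantile(window, 0.10, type = 7, names = FALSE)
  c(
    Trimmean = mean(window, trim = 0.25),
    Median   = stats::median(window),
    Prc25    = stats::quantile(window, 0.25, type = 7, names = FALSE),
    Prc75    = stats::quantile(window, 0.75, type = 7, names = FALSE),
    Kurtosis = krt,
    Skewness = skw,
    Std      = if (n > 1) stats::sd(window) else 0,
    Mad      = mean(abs(cen)),
    Geomean  = if (positive) exp(mean(log(window))) else NA_real_,
    Harmean  = if (positive) 1 / mean(1 / window) else NA_real_,
    Baseline = mean(window[window <= p10]),
    Max      = max(window),
    Min      = min(window),
    Mean     = mu
  )
}
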