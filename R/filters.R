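# FIR filter bank of the feature-extraction front end.
#
# Two filter families feed the pipeline:
#  * low-pass anti-aliasing FIR filters (LF, MF blocks), and
#  * band-pass interpolated-FIR (IFIR) filters (RF, EF blocks) realized as a
#    stretched-tap prototype: a short band-pass prototype of order N/SF whose
#    taps are spread SF samples apart, giving the full order N at 1/SF of the
#    per-sample cost.

#' Filter table of the deployed pipeline
#'
#' The six FIR filters of the extraction chain, one row per filter: the two
#' anti-aliasing low-passes per channel front end and the stretched-tap IFIR
#' band-passes isolating the respiration (0.1--0.5 Hz) and cardiac
#' (0.8--2.9 Hz) bands. `order` is the full filter order N (for IFIR filters
#' N = prototype order x stretch factor), `stretch` the IFIR stretch factor
#' SF (1 for plain FIR).
#'
#' @return A data frame with columns `name`, `kind`, `channel`, `fs`,
#'   `order`, `stretch`, `f_lo`, `f_hi` (Hz; `f_lo` is `NA` for low-pass).
#' @export
filter_table <- function() {
  data.frame(
    name    = c("LFECG", "MFECG", "RFECG", "LFTEB", "RFTEB", "EFTEB"),
    kind    = c("lowpass_antialias", "lowpass_antialias", "ifir_bandpass",
                "lowpass_antialias", "ifir_bandpass", "ifir_bandpass"),
    channel = c("ECG", "ECG", "ECG", "TEB", "TEB", "TEB"),
    fs      = c(250, 250, 250, 100, 100, 100),
    order   = c(100, 100, 1150, 100, 400, 400),
    stretch = c(1, 1, 25, 1, 10, 10),
    f_lo    = c(NA, NA, 0.1, NA, 0.1, 0.8),
    f_hi    = c(3, 30, 0.5, 3, 0.5, 2.9),
    stringsAsFactors = FALSE
  )
}

#' Design one filter of the extraction chain
#'
#' Realizes a filter from [filter_table()] as a linear-phase Hamming-windowed
#' FIR. Low-pass filters are normalized to unit DC gain. IFIR band-passes are
#' designed as a prototype of order `order/stretch` with band edges scaled up
#' by the stretch factor, normalized to unit gain at the band centre, then
#' stretched by inserting `stretch - 1` zeros between taps; only every
#' `stretch`-th tap is nonzero, which is what makes the per-sample cost
#' N*F/SF rather than N*F. Spectral images of the stretched prototype sit at
#' multiples of `fs/stretch` and are removed by the preceding anti-aliasing
#' low-pass in the chain.
#'
#' @param spec_name One of `"LFECG"`, `"MFECG"`, `"RFECG"`, `"LFTEB"`,
#'   `"RFTEB"`, `"EFTEB"`.
#' @param fs Sampling rate in Hz; must match the filter's channel (250 for
#'   ECG filters, 100 for TEB filters).
#' @return An object of class `filter_spec`: a list with `name`, `kind`,
#'   `order`, `cutoff_hz`, `stretch`, `fs`, and the tap vector
#'   `coefficients` (length `order + 1`).
#' @examples
#' f <- design_filter("LFECG", 250)
#' sum(f$coefficients)  # DC gain 1
#' @export
design_filter <- function(spec_name, fs) {
  tab <- filter_table()
  row <- tab[tab$name == spec_name, ]
  if (nrow(row) == 0L) {
    stop("unknown filter name: ", spec_name, call. = FALSE)
  }
  if (!isTRUE(all.equal(fs, row$fs))) {
    stop(sprintf("filter %s belongs to the %s channel (fs = %g Hz), got fs = %g",
                 spec_name, row$channel, row$fs, fs), call. = FALSE)
  }
  nyq <- fs / 2
  if (row$kind == "lowpass_antialias") {
    b <- signal::fir1(row$order, row$f_hi / nyq, type = "low")
    b <- b / sum(b)                       # unit DC gain
    cutoff <- row$f_hi
  } else {
    sf <- row$stretch
    n_proto <- row$order / sf
    stopifnot(n_proto == round(n_proto))
    edges <- c(row$f_lo, row$f_hi) * sf / nyq
    proto <- signal::fir1(n_proto, edges, type = "pass")
    fc <- (row$f_lo + row$f_hi) / 2 * sf  # normalize at stretched band centre
    g <- abs(sum(proto * exp(-1i * 2 * pi * fc / fs * seq_along(proto))))
    proto <- proto / g
    b <- numeric(row$order + 1)
    b[seq(1, row$order + 1, by = sf)] <- proto
    cutoff <- c(row$f_lo, row$f_hi)
  }
  structure(
    list(name = row$name, kind = row$kind, order = row$order,
         cutoff_hz = cutoff, stretch = row$stretch, fs = fs,
         coefficients = b),
    class = "filter_spec"
  )
}

#' Apply a FIR filter with group-delay compensation
#'
#' Linear convolution of the input with the filter taps, shifted back by the
#' linear-phase group delay (`order/2` samples) so output sample `n` is
#' aligned with input sample `n`. The input is edge-padded (replicating the
#' first and last samples) so the output has the same length as the input.
#'
#' @param filter A `filter_spec` from [design_filter()].
#' @param x Numeric input series; length must be at least `filter$order`.
#' @return Numeric vector the same length as `x`.
#' @export
apply_filter <- function(filter, x) {
  stopifnot(inherits(filter, "filter_spec"))
  n <- filter$order
  if (length(x) < n) {
    stop("input shorter than the filter order (", n, " samples)",
         call. = FALSE)
  }
  half_l <- floor(n / 2)
  half_r <- n - half_l
  xp <- c(rep(x[1], half_r), x, rep(x[length(x)], half_l))
  # causal FIR on the padded series; dropping the first n outputs both
  # trims the padding and undoes the n/2-sample group delay
  y <- stats::filter(xp, filter$coefficients, method = "convolution",
                     sides = 1)
  as.numeric(y[(n + 1):(n + length(x))])
}
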