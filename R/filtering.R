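# Shared preprocessing: zero-phase band filters, 60 Hz notch, analytic
# (Hilbert) amplitude/phase, z-scoring. All filters run forward-backward over
# a reflect-padded copy of the signal so that filtering is zero-phase and
# trial boundaries do not ring.

# forward-backward IIR filtering with reflection padding; pad_n should cover
# ~3 ringing time constants of the filter and is capped at n - 1.
filtfilt_reflect <- function(filt, x, pad_n = 300L) {
  n <- length(x)
  pad_n <- max(1L, min(as.integer(pad_n), n - 1L))
  # odd reflection about the end points keeps the padded signal continuous
  pre <- 2 * x[1] - x[(pad_n + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad_n)]
  xp <- c(pre, x, post)
  y <- signal::filter(filt, xp)
  y <- rev(as.numeric(signal::filter(filt, rev(as.numeric(y)))))
  y[(pad_n + 1):(pad_n + n)]
}

# RBJ cookbook second-order IIR notch
notch_biquad <- function(freq, fs, q = 30) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Notch out 60 Hz line contamination
#'
#' Applies a second-order IIR notch (quality factor 30) centred at 60 Hz,
#' forward and backward for zero phase distortion. A 60 Hz tone is attenuated
#' by well over 30 dB while tones 10 Hz away pass essentially unchanged.
#'
#' @param rec An [lfp_recording()].
#' @param q Notch quality factor; higher is narrower.
#' @return An `lfp_tbl` with the same metadata.
#' @export
notch_60hz <- function(rec, q = 30) {
  fs <- lfp_fs(rec)
  if (fs <= 120) stop("sampling rate must exceed 120 Hz to notch 60 Hz", call. = FALSE)
  filt <- notch_biquad(60, fs, q)
  # notch ringing time constant ~ q / (pi * 60) seconds
  pad_n <- ceiling(3 * q * fs / (pi * 60))
  new_lfp_like(rec, filtfilt_reflect(filt, rec$voltage, pad_n))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth band-pass applied forward-backward (zero-phase). In-band
#' tones pass with gain ~1; tones an octave outside the band are attenuated by
#' far more than 20 dB.
#'
#' @param rec An [lfp_recording()].
#' @param band A band name or `c(lo, hi)` in Hz; see [band_definition()].
#' @param order Butterworth prototype order (default 4).
#' @return An `lfp_tbl`; the band is recorded in attribute `band`.
#' @examples
#' rec <- lfp_recording(rnorm(2000), fs = 1000)
#' ripple <- bandpass(rec, "ripple")
#' @export
bandpass <- function(rec, band, order = 4) {
  fs <- lfp_fs(rec)
  band <- if (is.list(band)) band else band_definition(band)
  if (band$hi >= fs / 2) {
    stop("band upper edge ", band$hi, " Hz is at or above Nyquist (fs/2 = ",
         fs / 2, " Hz)", call. = FALSE)
  }
  filt <- signal::butter(order, c(band$lo, band$hi) / (fs / 2), type = "pass")
  # transient settles within a few cycles of the band's low edge
  pad_n <- ceiling(3 * fs / band$lo)
  out <- new_lfp_like(rec, filtfilt_reflect(filt, rec$voltage, pad_n))
  attr(out, "band") <- band
  out
}

# analytic signal via frequency-domain construction: zero the negative
# frequencies, double the positive ones
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous amplitude and phase (Hilbert analytic signal)
#'
#' Band-passes the recording (unless `band = NULL`, meaning the input is
#' already band-limited) and returns the analytic envelope and phase. Phase
#' follows the cosine convention: phase 0 at the band-passed signal's positive
#' peak, wrapped to (-pi, pi].
#'
#' @param rec An [lfp_recording()].
#' @param band Band to extract first, or `NULL` to skip internal band-passing.
#' @return A tibble of class `analytic_tbl` with columns `time_s`, `amplitude`,
#'   `phase`; attributes `fs` and `band`.
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 8 * seq(0, 5, by = 1e-3)), fs = 1000)
#' a <- analytic(rec, "theta")
#' median(a$amplitude)
#' @export
analytic <- function(rec, band = NULL) {
  fs <- lfp_fs(rec)
  if (!is.null(band)) rec <- bandpass(rec, band)
  bdef <- attr(rec, "band")
  if (!is.null(bdef) && nrow(rec) < 10 * fs / bdef$lo) {
    warning("series shorter than 10 cycles of the band's low edge; ",
            "envelope/phase estimates are edge-dominated", call. = FALSE)
  }
  z <- analytic_signal(rec$voltage)
  out <- tibble::new_tibble(
    list(time_s = rec$time_s, amplitude = Mod(z), phase = Arg(z)),
    nrow = nrow(rec), class = "analytic_tbl")
  attr(out, "fs") <- fs
  attr(out, "band") <- bdef
  attr(out, "channel_id") <- attr(rec, "channel_id")
  attr(out, "trial") <- attr(rec, "trial")
  out
}

#' z-score a series against a declared reference window
#'
#' Centres and scales by the mean and SD of the reference window only; by
#' default the whole series is its own reference, so the output has mean 0 and
#' SD 1. A baseline segment can instead serve as the reference, supporting
#' baseline-referenced normalization of stimulus trials.
#'
#' @param x Numeric vector, or a tibble with an `amplitude` (or `voltage`)
#'   column such as the output of [analytic()].
#' @param reference_window `NULL` (whole series) or `c(start, end)` sample
#'   indices (1-based, inclusive) of the normalization segment.
#' @param fs Sampling rate; taken from `x`'s attributes when present.
#' @return A tibble of class `zscored_tbl` with column `z`; attributes
#'   `mean_ref`, `sd_ref`, `reference_window`, `fs`.
#' @examples
#' zscore_series(c(1, 2, 3, 4, 5))
#' @export
zscore_series <- function(x, reference_window = NULL, fs = NULL) {
  if (is.data.frame(x)) {
    fs <- fs %||% attr(x, "fs")
    v <- x$amplitude %||% x$voltage
    if (is.null(v)) stop("data frame input needs an `amplitude` or `voltage` column", call. = FALSE)
  } else {
    v <- as.numeric(x)
  }
  n <- length(v)
  ref_idx <- if (is.null(reference_window)) seq_len(n) else {
    stopifnot(length(reference_window) == 2)
    seq(reference_window[1], reference_window[2])
  }
  m <- mean(v[ref_idx])
  s <- stats::sd(v[ref_idx])
  if (!is.finite(s) || s == 0) {
    stop("reference window has zero variance; cannot z-score", call. = FALSE)
  }
  out <- tibble::new_tibble(list(z = (v - m) / s), nrow = n,
                            class = "zscored_tbl")
  attr(out, "fs") <- fs
  attr(out, "mean_ref") <- m
  attr(out, "sd_ref") <- s
  attr(out, "reference_window") <-
    if (is.null(reference_window)) "whole_series" else reference_window
  out
}
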