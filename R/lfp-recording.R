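#' Construct an LFP recording
#'
#' An LFP recording is a tibble with columns `time_s` and `voltage`, carrying
#' the sampling rate and optional channel/trial annotations as attributes.
#' All filtering, detection and coupling functions in the package accept and
#' return this shape, so calls chain with the pipe.
#'
#' @param voltage Numeric vector of uniformly sampled voltage (arbitrary units).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_id Optional channel label.
#' @param trial Optional named list annotating the trial segment, e.g.
#'   `list(kind = "baseline", stimulus = "none", start_s = 0, end_s = 180)`.
#'   `kind` must be one of `"baseline"`, `"social"`, `"object"` when given.
#' @return A tibble of class `lfp_tbl` with columns `time_s`, `voltage`.
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 8 * seq(0, 1, by = 1 / 1000)), fs = 1000)
#' lfp_fs(rec)
#' @export
lfp_recording <- function(voltage, fs, channel_id = "ch1", trial = NULL) {
  stopifnot(is.numeric(voltage), length(voltage) >= 1)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (!all(is.finite(voltage))) {
    stop("`voltage` must be finite everywhere", call. = FALSE)
  }
  if (!is.null(trial) && !is.null(trial$kind) &&
      !trial$kind %in% c("baseline", "social", "object")) {
    stop("trial$kind must be one of 'baseline', 'social', 'object'", call. = FALSE)
  }
  out <- tibble::tibble(
    time_s = (seq_along(voltage) - 1) / fs,
    voltage = as.numeric(voltage)
  )
  structure(out,
    fs = fs, channel_id = channel_id, trial = trial,
    class = c("lfp_tbl", class(out))
  )
}

#' @rdname lfp_recording
#' @param rec An `lfp_tbl`.
#' @export
lfp_fs <- function(rec) {
  fs <- attr(rec, "fs")
  if (is.null(fs)) stop("recording has no sampling rate attribute `fs`", call. = FALSE)
  fs
}

#' @rdname lfp_recording
#' @export
lfp_channel <- function(rec) attr(rec, "channel_id") %||% NA_character_

# fast internal constructor: skips validation, reuses the time axis
new_lfp_fast <- function(voltage, fs, channel_id = "ch1", trial = NULL,
                         time_s = NULL) {
  n <- length(voltage)
  out <- tibble::new_tibble(
    list(time_s = time_s %||% (seq_len(n) - 1) / fs, voltage = voltage),
    nrow = n, class = "lfp_tbl")
  attr(out, "fs") <- fs
  attr(out, "channel_id") <- channel_id
  attr(out, "trial") <- trial
  out
}

# rebuild an lfp_tbl with new samples, preserving metadata
new_lfp_like <- function(rec, voltage) {
  new_lfp_fast(voltage, fs = attr(rec, "fs"),
               channel_id = attr(rec, "channel_id"),
               trial = attr(rec, "trial"),
               time_s = rec$time_s)
}

#' Canonical frequency bands
#'
#' The four bands used throughout: ripple (140-220 Hz), theta (4-12 Hz),
#' low gamma (25-50 Hz) and mid gamma (50-100 Hz).
#'
#' @param name One of `"ripple"`, `"theta"`, `"low_gamma"`, `"mid_gamma"`, or
#'   a numeric length-2 vector `c(lo, hi)` for a custom band.
#' @return A named list with elements `name`, `lo`, `hi`.
#' @examples
#' band_definition("ripple")
#' @export
band_definition <- function(name) {
  canon <- list(
    ripple    = c(140, 220),
    theta     = c(4, 12),
    low_gamma = c(25, 50),
    mid_gamma = c(50, 100)
  )
  if (is.numeric(name)) {
    stopifnot(length(name) == 2, name[1] > 0, name[2] > name[1])
    return(list(name = "custom", lo = name[1], hi = name[2]))
  }
  name <- match.arg(name, names(canon))
  list(name = name, lo = canon[[name]][1], hi = canon[[name]][2])
}

#' @importFrom rlang %||%
NULL
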