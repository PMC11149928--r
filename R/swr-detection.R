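# SWR event detection on the z-scored ripple-band envelope.
#
# Detection rule: maximal runs of z strictly exceeding the threshold,
# boundary-extended outward to the boundary threshold crossings, merged when
# separated by at most the merge gap, then filtered by minimum duration.
# Sample intervals are half-open [start, end); duration = n_samples / fs, so
# the integral (sum of z over the span) and the duration count the same
# samples.

#' Detection parameters for sharp-wave-ripple events
#'
#' Defaults implement the rule "events exceeding three standard deviations for
#' a minimum of 15 ms, with events within 15 ms of one another merged".
#'
#' @param threshold_sd Detection threshold on the z-scored envelope (SD units).
#' @param min_duration_ms Minimum supra-threshold duration (ms); applied to
#'   the merged span.
#' @param merge_gap_ms Maximum end-to-start gap for merging (ms, inclusive).
#' @param boundary_sd Threshold defining event start/end; must not exceed
#'   `threshold_sd`. With the default (equal to `threshold_sd`) the event span
#'   is exactly the supra-threshold run; a lower value (e.g. 1) extends the
#'   span to the envelope's flanks.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(threshold_sd = 3, min_duration_ms = 15,
                             merge_gap_ms = 15, boundary_sd = threshold_sd) {
  stopifnot(threshold_sd > 0, min_duration_ms > 0, merge_gap_ms >= 0,
            boundary_sd <= threshold_sd, boundary_sd > 0)
  structure(list(threshold_sd = threshold_sd,
                 min_duration_ms = min_duration_ms,
                 merge_gap_ms = merge_gap_ms,
                 boundary_sd = boundary_sd),
            class = "detection_params")
}

# maximal runs where cond is TRUE -> matrix of [start, end) sample indices
runs_true <- function(cond) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  cbind(start = starts[keep], end_excl = ends[keep] + 1)
}

events_from_spans <- function(z, fs, spans) {
  n_ev <- nrow(spans)
  if (n_ev == 0) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                          duration_ms = numeric(), peak_z = numeric(),
                          integral_z = numeric(), peak_time_s = numeric()))
  }
  a <- unname(spans[, 1])
  b <- unname(spans[, 2]) - 1  # last included sample
  cs <- c(0, cumsum(z))
  peak <- numeric(n_ev)
  pk_idx <- integer(n_ev)
  for (i in seq_len(n_ev)) {
    seg <- z[a[i]:b[i]]
    j <- which.max(seg)
    peak[i] <- seg[j]
    pk_idx[i] <- a[i] + j - 1L
  }
  tibble::new_tibble(list(
    start_s = (a - 1) / fs,
    end_s = b / fs,
    duration_ms = (b - a + 1) / fs * 1000,
    peak_z = peak,
    integral_z = cs[b + 1] - cs[a],
    peak_time_s = (pk_idx - 1) / fs
  ), nrow = n_ev)
}

#' Detect SWR events on a z-scored ripple-band envelope
#'
#' @param z_env A [zscore_series()] result (needs a sampling rate), or a plain
#'   numeric z vector with `fs` supplied.
#' @param params A [detection_params()].
#' @param fs Sampling rate; required when `z_env` carries none.
#' @return A tibble of class `swr_events`, one row per event, sorted and
#'   non-overlapping: `start_s`, `end_s`, `duration_ms`, `peak_z`,
#'   `integral_z`, `peak_time_s`.
#' @examples
#' z <- numeric(1000); z[101:130] <- 4
#' detect_events(z, detection_params(), fs = 1000)
#' @export
detect_events <- function(z_env, params = detection_params(), fs = NULL) {
  z <- if (is.data.frame(z_env)) z_env$z else as.numeric(z_env)
  fs <- fs %||% attr(z_env, "fs")
  if (is.null(fs)) stop("sampling rate `fs` is required for event detection", call. = FALSE)
  if (length(z) == 0) {
    return(new_swr_events(events_from_spans(numeric(), fs,
                                            matrix(numeric(), ncol = 2)), params, fs))
  }
  # boundary runs that contain at least one supra-threshold sample are
  # exactly the threshold runs extended outward to the boundary crossings
  spans <- runs_true(z > params$boundary_sd)
  if (nrow(spans) > 0) {
    has_core <- vapply(seq_len(nrow(spans)), function(i) {
      any(z[spans[i, 1]:(spans[i, 2] - 1)] > params$threshold_sd)
    }, logical(1))
    spans <- spans[has_core, , drop = FALSE]
  }
  spans <- merge_spans(spans, params$merge_gap_ms, fs)
  if (nrow(spans) > 0) {
    min_n <- params$min_duration_ms / 1000 * fs
    long_enough <- (spans[, 2] - spans[, 1]) >= min_n
    spans <- spans[long_enough, , drop = FALSE]
  }
  new_swr_events(events_from_spans(z, fs, spans), params, fs)
}

new_swr_events <- function(tbl, params, fs) {
  structure(tbl, params = params, fs = fs,
            class = c("swr_events", class(tbl)))
}

# transitive merge of [start, end) spans when gap (samples) <= merge_gap
merge_spans <- function(spans, merge_gap_ms, fs) {
  if (nrow(spans) <= 1) return(spans)
  gap_max <- merge_gap_ms / 1000 * fs
  out <- spans[1, , drop = FALSE]
  for (i in 2:nrow(spans)) {
    gap <- spans[i, 1] - out[nrow(out), 2]
    if (gap <= gap_max) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], spans[i, 2])
    } else {
      out <- rbind(out, spans[i, , drop = FALSE])
    }
  }
  out
}

#' Merge nearby events
#'
#' Coalesces, transitively, any events whose end-to-start gap is at most
#' `merge_gap_ms`. Peak, integral and duration are recomputed over the merged
#' span (the z series the events came from must be supplied for that).
#'
#' @param events An `swr_events` tibble sorted by `start_s`.
#' @param merge_gap_ms Maximum gap (ms), inclusive.
#' @param z_env z series the events were detected on; defaults to recomputing
#'   features as sums/maxima of the constituent events when omitted (exact
#'   when gaps contain no supra-boundary samples).
#' @param fs Sampling rate; taken from `events` when present.
#' @return An `swr_events` tibble.
#' @export
merge_events <- function(events, merge_gap_ms, z_env = NULL, fs = NULL) {
  fs <- fs %||% attr(events, "fs")
  if (is.null(fs)) stop("`fs` required", call. = FALSE)
  if (nrow(events) == 0) return(events)
  if (is.unsorted(events$start_s)) stop("events must be sorted by start_s", call. = FALSE)
  spans <- cbind(round(events$start_s * fs) + 1, round(events$end_s * fs) + 1)
  merged <- merge_spans(spans, merge_gap_ms, fs)
  if (!is.null(z_env)) {
    z <- if (is.data.frame(z_env)) z_env$z else as.numeric(z_env)
    out <- events_from_spans(z, fs, merged)
  } else {
    # group events by merged span and combine features
    grp <- findInterval(round(events$start_s * fs) + 1, merged[, 1])
    out <- events |>
      tibble::as_tibble() |>
      dplyr::mutate(.grp = grp) |>
      dplyr::group_by(.data$.grp) |>
      dplyr::summarise(
        start_s = min(.data$start_s),
        end_s = max(.data$end_s),
        peak_z = max(.data$peak_z),
        integral_z = sum(.data$integral_z),
        peak_time_s = .data$peak_time_s[which.max(.data$peak_z)],
        .groups = "drop"
      ) |>
      dplyr::mutate(duration_ms = (.data$end_s - .data$start_s) * 1000) |>
      dplyr::select("start_s", "end_s", "duration_ms", "peak_z",
                    "integral_z", "peak_time_s")
  }
  new_swr_events(out, attr(events, "params"), fs)
}

#' Per-event features over an interval
#'
#' Computes the event features over the half-open sample span covering
#' `[start_s, end_s)`: peak z, integral (sum of z over the span's samples),
#' duration from the sample count.
#'
#' @param z_env z series (vector or [zscore_series()] output).
#' @param start_s,end_s Interval in seconds; `end_s` exclusive.
#' @param fs Sampling rate; taken from `z_env` when present.
#' @return A one-row `swr_events` tibble.
#' @examples
#' event_features(rep(5, 100), 0, 0.03, fs = 1000)
#' @export
event_features <- function(z_env, start_s, end_s, fs = NULL) {
  z <- if (is.data.frame(z_env)) z_env$z else as.numeric(z_env)
  fs <- fs %||% attr(z_env, "fs")
  if (is.null(fs)) stop("`fs` required", call. = FALSE)
  a <- round(start_s * fs) + 1
  b <- round(end_s * fs)
  if (b < a || a < 1 || b > length(z)) {
    stop("interval [", start_s, ", ", end_s, ") empty or outside the series", call. = FALSE)
  }
  events_from_spans(z, fs, cbind(a, b + 1))
}

#' Summarize SWR events over a trial
#'
#' Event rate (events/s over the whole trial), raw count, and per-trial means
#' of peak amplitude, duration and integral. With no events the rate is 0 and
#' the means are `NA` (flagged undefined, never imputed).
#'
#' @param events An `swr_events` tibble.
#' @param trial_duration_s Trial length in seconds (> 0).
#' @return A one-row tibble of class `swr_summary`: `n_events`, `rate_hz`,
#'   `mean_peak_z`, `mean_duration_ms`, `mean_integral`, `trial_duration_s`.
#' @examples
#' z <- numeric(3000); z[101:160] <- 4
#' summarize_trial(detect_events(z, fs = 1000), trial_duration_s = 3)
#' @export
summarize_trial <- function(events, trial_duration_s) {
  if (!is.numeric(trial_duration_s) || trial_duration_s <= 0) {
    stop("`trial_duration_s` must be positive", call. = FALSE)
  }
  n <- nrow(events)
  out <- tibble::tibble(
    n_events = n,
    rate_hz = n / trial_duration_s,
    mean_peak_z = if (n > 0) mean(events$peak_z) else NA_real_,
    mean_duration_ms = if (n > 0) mean(events$duration_ms) else NA_real_,
    mean_integral = if (n > 0) mean(events$integral_z) else NA_real_,
    trial_duration_s = trial_duration_s
  )
  structure(out, channel_id = attr(events, "channel_id"),
            class = c("swr_summary", class(out)))
}

#' Normalize a stimulus-trial summary to its baseline
#'
#' Feature-wise ratios stimulus / baseline. Features whose baseline value is 0
#' or undefined come back `NA` (flagged, never silently dropped).
#'
#' @param stim,base One-row `swr_summary` tibbles from the same
#'   session/channel.
#' @return A one-row tibble of class `swr_normalized` with columns
#'   `n_events`, `rate_hz`, `mean_peak_z`, `mean_duration_ms`, `mean_integral`
#'   holding the ratios.
#' @export
normalize_to_baseline <- function(stim, base) {
  cs <- attr(stim, "channel_id"); cb <- attr(base, "channel_id")
  if (!is.null(cs) && !is.null(cb) && !identical(cs, cb)) {
    stop("stimulus and baseline summaries come from different channels (",
         cs, " vs ", cb, ")", call. = FALSE)
  }
  feats <- c("n_events", "rate_hz", "mean_peak_z", "mean_duration_ms",
             "mean_integral")
  ratio <- function(f) {
    b <- base[[f]]
    if (is.na(b) || b == 0) NA_real_ else stim[[f]] / b
  }
  out <- tibble::as_tibble(stats::setNames(lapply(feats, ratio), feats))
  structure(out, class = c("swr_normalized", class(out)))
}

#' Full SWR detection pipeline on a raw recording
#'
#' Composes the published preprocessing: 60 Hz notch, ripple-band (140-220 Hz)
#' band-pass, Hilbert envelope, z-scoring, then event detection.
#'
#' @param rec An [lfp_recording()].
#' @param params A [detection_params()].
#' @param notch Apply the 60 Hz notch first (default TRUE for the SWR path).
#' @param reference_window Passed to [zscore_series()]; default self-referenced.
#' @return An `swr_events` tibble (carries the channel id).
#' @examples
#' bg <- generate_background(10, 1000, seed = 1)
#' out <- inject_ripples(bg, ripple_spec(rate = 0.3, amplitude_z = 6), seed = 2)
#' detect_swr(out$recording)
#' @export
detect_swr <- function(rec, params = detection_params(), notch = TRUE,
                       reference_window = NULL) {
  if (notch) rec <- notch_60hz(rec)
  env <- analytic(rec, "ripple")
  z <- zscore_series(env, reference_window = reference_window)
  ev <- detect_events(z, params, fs = lfp_fs(rec))
  attr(ev, "channel_id") <- attr(rec, "channel_id")
  ev
}
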