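# Independent reference implementations and fixture builders used across the
# suite. The naive detector scans sample by sample, merges by repeated
# pairwise passes, and never shares code with the package's rle-based path.

# naive per-sample SWR detector: returns a data.frame of events
naive_detect <- function(z, fs, params = detection_params()) {
  n <- length(z)
  # 1. maximal runs above the boundary threshold (per-sample scan)
  runs <- list()
  cur <- NULL
  for (i in seq_len(n)) {
    if (z[i] > params$boundary_sd) {
      if (is.null(cur)) cur <- c(i, i) else cur[2] <- i
    } else if (!is.null(cur)) {
      runs[[length(runs) + 1]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  # 2. keep runs containing at least one supra-threshold sample
  runs <- Filter(function(r) {
    any_over <- FALSE
    for (i in r[1]:r[2]) if (z[i] > params$threshold_sd) any_over <- TRUE
    any_over
  }, runs)
  # 3. repeated pairwise merge passes until stable
  gap_max <- params$merge_gap_ms / 1000 * fs
  repeat {
    changed <- FALSE
    if (length(runs) >= 2) {
      out <- list(runs[[1]])
      for (i in 2:length(runs)) {
        last <- out[[length(out)]]
        gap <- runs[[i]][1] - last[2] - 1
        if (gap <= gap_max) {
          out[[length(out)]] <- c(last[1], max(last[2], runs[[i]][2]))
          changed <- TRUE
        } else {
          out[[length(out) + 1]] <- runs[[i]]
        }
      }
      runs <- out
    }
    if (!changed) break
  }
  # 4. minimum-duration filter on the merged span
  min_n <- params$min_duration_ms / 1000 * fs
  runs <- Filter(function(r) (r[2] - r[1] + 1) >= min_n, runs)
  if (length(runs) == 0) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      duration_ms = numeric(), peak_z = numeric(),
                      integral_z = numeric()))
  }
  do.call(rbind, lapply(runs, function(r) {
    seg <- z[r[1]:r[2]]
    data.frame(start_s = (r[1] - 1) / fs, end_s = r[2] / fs,
               duration_ms = (r[2] - r[1] + 1) / fs * 1000,
               peak_z = max(seg), integral_z = sum(seg))
  }))
}

# random z-envelope with sub- and supra-threshold runs of varied width/gap
random_envelope <- function(n, seed) {
  set.seed(seed)
  z <- rnorm(n, 0, 1.2)
  k <- sample(0:8, 1)
  for (i in seq_len(k)) {
    w <- sample(3:45, 1)
    a <- sample(1:(n - w), 1)
    z[a:(a + w - 1)] <- z[a:(a + w - 1)] + runif(1, 1.5, 6)
  }
  z
}

# fraction of true intervals overlapped by at least one detected event
interval_recall <- function(truth, events) {
  if (nrow(truth) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(events$start_s < truth$end_s[i] & events$end_s > truth$start_s[i])
  }, logical(1))
  mean(hit)
}

# detected events not overlapping any true interval, per second
false_event_rate <- function(truth, events, duration_s) {
  if (nrow(events) == 0) return(0)
  fp <- vapply(seq_len(nrow(events)), function(i) {
    !any(truth$start_s < events$end_s[i] & truth$end_s > events$start_s[i])
  }, logical(1))
  sum(fp) / duration_s
}

# gain of a filter operation for a pure tone, measured away from the edges
tone_gain <- function(filter_fn, freq, fs = 1000, dur = 10) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  y <- filter_fn(lfp_recording(x, fs))$voltage
  core <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
  sd(y[core]) / sd(x[core])
}

circ_dist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
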