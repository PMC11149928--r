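# Detection rule: 3 SD threshold, 15 ms minimum, 15 ms merge; features

fs <- 1000

test_that("all-zero and empty envelopes yield no events", {
  expect_equal(nrow(detect_events(numeric(1000), fs = fs)), 0)
  expect_equal(nrow(detect_events(numeric(0), fs = fs)), 0)
  expect_error(detect_events(numeric(100)), "fs")
})

test_that("a 30 ms supra-threshold run is one event with exact features", {
  z <- numeric(1000)
  z[101:130] <- 4
  ev <- detect_events(z, fs = fs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_ms, 30)
  expect_equal(ev$peak_z, 4)
  expect_equal(ev$integral_z, 120)
  expect_equal(ev$start_s, 0.1)
  expect_equal(ev$end_s, 0.13)
})

test_that("runs shorter than the 15 ms minimum are rejected", {
  z <- numeric(1000)
  z[101:110] <- 4  # 10 ms
  expect_equal(nrow(detect_events(z, fs = fs)), 0)
})

test_that("runs within 15 ms merge; runs 20 ms apart stay separate", {
  z <- numeric(1000)
  z[101:120] <- 4          # 20 ms
  z[131:150] <- 4          # 10 ms gap
  ev <- detect_events(z, fs = fs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_ms, 50)

  z2 <- numeric(1000)
  z2[101:120] <- 4
  z2[141:160] <- 4         # 20 ms gap
  expect_equal(nrow(detect_events(z2, fs = fs)), 2)
})

test_that("a sub-minimum pair that merges into >= 15 ms counts as one event", {
  z <- numeric(1000)
  z[101:110] <- 4          # 10 ms
  z[116:125] <- 4          # 5 ms gap, merged span 25 ms
  ev <- detect_events(z, fs = fs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_ms, 25)
})

test_that("merging is transitive, idempotent and order-checked", {
  z <- numeric(2000)
  z[101:120] <- 4; z[131:150] <- 4; z[161:180] <- 4  # chain, 10 ms gaps
  ev <- detect_events(z, fs = fs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 0.1)
  expect_equal(ev$end_s, 0.18)

  # idempotence on already-merged events
  once <- merge_events(ev, 15, z_env = z, fs = fs)
  twice <- merge_events(once, 15, z_env = z, fs = fs)
  expect_equal(tidy(once), tidy(twice))

  # empty input passes through; unsorted input errors
  empty <- detect_events(numeric(100), fs = fs)
  expect_equal(nrow(merge_events(empty, 15, fs = fs)), 0)
  bad <- ev[c(1, 1), ]
  bad$start_s <- c(0.5, 0.1)
  expect_error(merge_events(bad, 15, fs = fs), "sorted")
})

test_that("merged features are recomputed over the merged span", {
  z <- numeric(1000)
  z[101:120] <- 4; z[131:150] <- 5
  ev <- detect_events(z, fs = fs)
  expect_equal(ev$peak_z, 5)
  expect_equal(ev$integral_z, sum(z[101:150]))  # gap samples included
})

test_that("event_features matches closed-form sums", {
  expect_equal(event_features(rep(5, 100), 0, 0.03, fs = fs)$integral_z, 150)
  expect_equal(event_features(rep(5, 100), 0, 0.03, fs = fs)$peak_z, 5)
  # triangular ramp 0 -> 6 -> 0 over 31 samples
  tri <- c(seq(0, 6, length.out = 16), seq(6, 0, length.out = 16)[-1])
  z <- c(numeric(10), tri, numeric(10))
  f <- event_features(z, 10 / fs, 41 / fs, fs = fs)
  expect_equal(f$integral_z, sum(tri))
  expect_equal(f$peak_z, 6)
  # single sample
  f1 <- event_features(c(0, 4, 0), 1 / fs, 2 / fs, fs = fs)
  expect_equal(f1$duration_ms, 1)
  expect_equal(f1$integral_z, 4)
  expect_error(event_features(z, 0.5, 0.5, fs = fs), "empty")
})

test_that("lower boundary threshold extends event spans to envelope flanks", {
  z <- numeric(1000)
  z[96:100] <- 2; z[101:130] <- 4; z[131:140] <- 2
  ev <- detect_events(z, detection_params(boundary_sd = 1), fs = fs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 0.095)
  expect_equal(ev$end_s, 0.14)
  # without a supra-threshold core, a boundary-level run is not an event
  z2 <- numeric(1000); z2[101:160] <- 2
  expect_equal(nrow(detect_events(z2, detection_params(boundary_sd = 1), fs = fs)), 0)
})

test_that("detection matches the naive per-sample oracle on random envelopes", {
  for (s in 1:60) {
    z <- random_envelope(sample(500:3000, 1), seed = s)
    got <- detect_events(z, fs = fs)
    ref <- naive_detect(z, fs)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref) > 0) {
      expect_equal(got$start_s, ref$start_s)
      expect_equal(got$end_s, ref$end_s)
      expect_equal(got$peak_z, ref$peak_z)
      expect_equal(got$integral_z, ref$integral_z)
    }
  }
})

test_that("event count is monotone in threshold and merge gap", {
  for (s in 1:10) {
    z <- random_envelope(2000, seed = 100 + s)
    n_thr <- vapply(c(2, 3, 4, 5), function(th) {
      nrow(detect_events(z, detection_params(threshold_sd = th,
                                             boundary_sd = th), fs = fs))
    }, numeric(1))
    expect_true(all(diff(n_thr) <= 0))
    # with the minimum-duration filter below every run width (1 sample at
    # 1 kHz), merging can only ever coalesce events, so the count is
    # non-increasing in the gap
    n_gap <- vapply(c(0, 5, 15, 40, 100), function(g) {
      nrow(detect_events(z, detection_params(min_duration_ms = 1,
                                             merge_gap_ms = g), fs = fs))
    }, numeric(1))
    expect_true(all(diff(n_gap) <= 0))
  }
})

test_that("trial summaries implement rate, means and the empty-trial flags", {
  z <- numeric(600 * fs)
  centers <- seq(5, 595, length.out = 10)
  for (cc in centers) z[(cc * fs):(cc * fs + 29)] <- 4
  ev <- detect_events(z, fs = fs)
  sm <- summarize_trial(ev, 300)
  expect_equal(sm$n_events, 10)
  expect_equal(sm$rate_hz, 10 / 300)

  sm0 <- summarize_trial(detect_events(numeric(1000), fs = fs), 180)
  expect_equal(sm0$rate_hz, 0)
  expect_true(is.na(sm0$mean_integral))
  expect_error(summarize_trial(ev, -1), "positive")

  # mean of per-event integrals
  z2 <- numeric(2000)
  z2[101:125] <- 4    # integral 100
  z2[1001:1035] <- 4  # integral 140
  sm2 <- summarize_trial(detect_events(z2, fs = fs), 2)
  expect_equal(sm2$mean_integral, 120)
})

test_that("baseline normalization is ratio-wise with degenerate flags", {
  z <- numeric(2000); z[101:130] <- 4
  base <- summarize_trial(detect_events(z, fs = fs), 100)
  stim <- summarize_trial(detect_events(c(z, z), fs = fs), 100)
  same <- normalize_to_baseline(base, base)
  expect_true(all(vapply(c("rate_hz", "mean_peak_z", "mean_integral"),
                         function(f) same[[f]] == 1, logical(1))))
  norm <- normalize_to_baseline(stim, base)
  expect_equal(norm$rate_hz, 2)
  expect_equal(norm$n_events, 2)

  empty <- summarize_trial(detect_events(numeric(1000), fs = fs), 100)
  flagged <- normalize_to_baseline(stim, empty)
  expect_true(is.na(flagged$rate_hz))
  expect_true(is.na(flagged$mean_integral))

  a <- base; attr(a, "channel_id") <- "ch1"
  b <- base; attr(b, "channel_id") <- "ch2"
  expect_error(normalize_to_baseline(a, b), "channels")
})

test_that("injected bursts are recovered end to end with few false positives", {
  recalls <- numeric(3); fps <- numeric(3)
  for (s in 1:3) {
    bg <- generate_background(60, 1000, noise_spec(exponent = 1), seed = s)
    out <- inject_ripples(bg, ripple_spec(rate = 0.3, amplitude_z = 6,
                                          duration_ms = 50), seed = s + 10)
    ev <- detect_swr(out$recording)
    recalls[s] <- interval_recall(out$ground_truth, ev)
    ev0 <- detect_swr(bg)
    fps[s] <- nrow(ev0) / 60
  }
  expect_gte(mean(recalls), 0.95)
  expect_lte(mean(fps), 0.05)
})
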