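# Session orchestration: bookkeeping, nesting, determinism, group recovery

make_session_inputs <- function(channels = "ch1", seed = 1, seg_s = 30,
                                rates = c(baseline = 0.3, mother = 0.6,
                                          novel_mother = 0.3)) {
  trials <- tibble::tibble(
    segment = names(rates),
    kind = c("baseline", "social", "social"),
    stimulus = c("none", "mother", "novel_mother"),
    duration_s = seg_s
  )
  design <- session_design("m1", trials = trials, channels = channels)
  recs <- purrr::map_dfr(names(rates), function(seg) {
    purrr::map_dfr(channels, function(ch) {
      bg <- generate_background(seg_s, 1000, seed = seed, channel_id = ch)
      inj <- inject_ripples(bg, ripple_spec(rate = rates[[seg]]), seed = seed + 7)
      tibble::tibble(segment = seg, channel_id = ch,
                     recording = list(inj$recording))
    })
  })
  list(design = design, recs = recs)
}

test_that("one session yields the expected tidy rows and normalization", {
  inp <- make_session_inputs()
  out <- run_session(inp$design, inp$recs)
  # 3 segments x (5 SWR features + 1 PAC feature)
  expect_equal(nrow(out), 18)
  expect_equal(sum(out$feature_name == "mi_mid_gamma"), 3)
  norm_rows <- out[!is.na(out$baseline_normalized_value), ]
  # 2 stimulus segments x 5 SWR features carry normalized values
  expect_equal(nrow(norm_rows), 10)
  expect_true(all(norm_rows$stimulus %in% c("mother", "novel_mother")))
  expect_setequal(unique(out$stimulus), c("baseline", "mother", "novel_mother"))
  # same recording for baseline and novel_mother (same seed) -> ratio 1
  nm <- out[out$stimulus == "novel_mother" & out$feature_name == "rate_hz", ]
  expect_equal(nm$baseline_normalized_value, 1)
})

test_that("a baseline-only design yields raw rows without normalization", {
  trials <- tibble::tibble(segment = "baseline", kind = "baseline",
                           stimulus = "none", duration_s = 20)
  design <- session_design("m1", trials = trials)
  bg <- generate_background(20, 1000, seed = 2)
  recs <- tibble::tibble(segment = "baseline", channel_id = "ch1",
                         recording = list(bg))
  out <- run_session(design, recs)
  expect_true(all(is.na(out$baseline_normalized_value)))
  expect_equal(nrow(out), 6)
})

test_that("identical signals on two channels give identical features", {
  inp <- make_session_inputs(channels = c("ch1", "ch2"), seg_s = 20)
  out <- run_session(inp$design, inp$recs)
  wide <- tidyr::pivot_wider(out, names_from = channel_id,
                             values_from = c(raw_value,
                                             baseline_normalized_value))
  expect_equal(wide$raw_value_ch1, wide$raw_value_ch2)
})

test_that("missing segment recordings raise a structured error naming the gap", {
  inp <- make_session_inputs()
  expect_error(run_session(inp$design, inp$recs[-2, ]), "mother/ch1")
})

test_that("the pipeline is deterministic: identical runs, byte-identical tables", {
  inp <- make_session_inputs(seed = 9, seg_s = 20)
  out1 <- run_session(inp$design, inp$recs)
  out2 <- run_session(inp$design, inp$recs)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_table_csv(out1, f1); write_table_csv(out2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  sim1 <- batch_simulate_and_analyze(n_animals = 2, n_channels = 1,
                                     segments = c(baseline = 15, stimulus = 15),
                                     fs = 500, seed = 4)
  sim2 <- batch_simulate_and_analyze(n_animals = 2, n_channels = 1,
                                     segments = c(baseline = 15, stimulus = 15),
                                     fs = 500, seed = 4)
  expect_identical(sim1$results, sim2$results)
})

test_that("the run manifest records parameters and the mixed-model formula", {
  inp <- make_session_inputs(seg_s = 20)
  out <- run_session(inp$design, inp$recs)
  man <- attr(out, "manifest")
  expect_equal(man$detection$threshold_sd, 3)
  expect_match(man$model_formula, "animal_id")
  tmp <- tempfile(fileext = ".json")
  write_run_manifest(man, tmp)
  expect_equal(jsonlite::read_json(tmp)$detection$min_duration_ms, 15)
})

test_that("a 2x stimulus rate multiplier is recovered in normalized rates", {
  sim <- batch_simulate_and_analyze(
    n_animals = 10, n_channels = 1, segments = c(baseline = 60, stimulus = 60),
    fs = 500, rate_multiplier = c(cre_gi = 2), seed = 12)
  r <- dplyr::filter(sim$results, feature_name == "rate_hz",
                     stimulus == "stimulus")
  expect_equal(mean(r$baseline_normalized_value), 2, tolerance = 0.1)
  expect_equal(sim$truth$true_rate_hz[sim$truth$segment == "stimulus"][1], 0.6)
})

test_that("a null cohort has normalized features near one", {
  sim <- batch_simulate_and_analyze(
    n_animals = 6, n_channels = 1, segments = c(baseline = 60, stimulus = 60),
    fs = 500, rate_multiplier = c(cre_only = 1, cre_gi = 1), seed = 3)
  r <- dplyr::filter(sim$results, feature_name == "rate_hz",
                     stimulus == "stimulus")
  expect_equal(mean(r$baseline_normalized_value), 1, tolerance = 0.2)
})

test_that("per-stimulus coupling differences are recovered in MI ordering", {
  sim <- batch_simulate_and_analyze(
    n_animals = 10, n_channels = 1,
    segments = c(baseline = 30, mother = 30, novel_mother = 30),
    fs = 500, baseline_rate_hz = 0, rate_multiplier = c(cre_only = 1),
    coupling = c(baseline = 0.1, mother = 0.6, novel_mother = 0.3),
    noise = noise_spec(rms = 0.3), seed = 6)
  mi <- dplyr::filter(sim$results, feature_name == "mi_mid_gamma")
  wide <- tidyr::pivot_wider(mi, id_cols = animal_id, names_from = stimulus,
                             values_from = raw_value)
  expect_gte(sum(wide$mother > wide$novel_mother), 9)
})

test_that("invalid effect multipliers are rejected", {
  expect_error(batch_simulate_and_analyze(rate_multiplier = c(a = -1), seed = 1),
               ">= 0")
})

test_that("permutation test separates shifted groups and calibrates the null", {
  set.seed(8)
  x <- c(rnorm(5), rnorm(5) + 5)
  g <- rep(c("a", "b"), each = 5)
  expect_lt(perm_test_two_group(x, g)$p_value, 0.01)
  x0 <- rnorm(10)
  p0 <- perm_test_two_group(x0, g)$p_value
  expect_gte(p0, 2 / choose(10, 5))
})
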