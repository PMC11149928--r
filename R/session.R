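# Session orchestration: the study design is a baseline segment followed by
# stimulus segments (social: 3 min baseline + 5 min interaction; object:
# 1 min baseline + 2 min exposure), recorded on one or more electrodes per
# animal. The pipeline runs the SWR and PAC stages per channel x segment,
# normalizes stimulus features to the session baseline, and emits one tidy
# row per (channel x segment x feature) — channels are never averaged, so the
# table is ready for mixed-effects fits with a random effect of animal.

#' Declare a recording session
#'
#' @param animal_id Animal label.
#' @param genotype Group label, e.g. `"cre_only"` or `"cre_gi"`.
#' @param drug Treatment label, e.g. `"vehicle"` or `"cno"`.
#' @param trials A tibble with columns `segment` (unique label; the baseline
#'   segment must be named `"baseline"`), `kind` (`"baseline"`, `"social"` or
#'   `"object"`), `stimulus` (`"none"`, `"mother"`, `"novel_mother"`,
#'   `"object"`), `duration_s`.
#' @param channels Character vector of electrode/channel ids.
#' @return A `session_design` list.
#' @examples
#' session_design("m1", trials = social_trials())
#' @export
session_design <- function(animal_id, genotype = "cre_only", drug = "vehicle",
                           trials = social_trials(), channels = "ch1") {
  stopifnot(is.data.frame(trials),
            all(c("segment", "kind", "stimulus", "duration_s") %in% names(trials)),
            all(trials$duration_s > 0),
            !anyDuplicated(trials$segment))
  if (any(trials$kind != "baseline") && !"baseline" %in% trials$segment) {
    stop("every stimulus segment needs a preceding baseline in the session",
         call. = FALSE)
  }
  structure(list(animal_id = animal_id, genotype = genotype, drug = drug,
                 trials = tibble::as_tibble(trials), channels = channels),
            class = "session_design")
}

#' @rdname session_design
#' @param stimuli Stimulus labels for the social trials.
#' @param baseline_s,stimulus_s Segment durations in seconds; defaults are
#'   the study's 3 min baseline and 5 min social-interaction periods.
#' @export
social_trials <- function(stimuli = c("mother", "novel_mother"),
                          baseline_s = 180, stimulus_s = 300) {
  tibble::tibble(
    segment = c("baseline", stimuli),
    kind = c("baseline", rep("social", length(stimuli))),
    stimulus = c("none", stimuli),
    duration_s = c(baseline_s, rep(stimulus_s, length(stimuli)))
  )
}

#' @rdname session_design
#' @export
object_trials <- function(baseline_s = 60, stimulus_s = 120) {
  tibble::tibble(
    segment = c("baseline", "object"),
    kind = c("baseline", "object"),
    stimulus = c("none", "object"),
    duration_s = c(baseline_s, stimulus_s)
  )
}

swr_feature_names <- c("n_events", "rate_hz", "mean_peak_z",
                       "mean_duration_ms", "mean_integral")

#' Run the full analysis over one session
#'
#' Per channel and segment: SWR detection (notch, ripple band-pass, Hilbert
#' envelope, z-score, threshold rule) summarized over the segment, normalized
#' to the session's baseline segment on the same channel; optionally a PAC
#' profile per segment. Deterministic given inputs.
#'
#' @param design A [session_design()].
#' @param recordings A tibble with columns `segment`, `channel_id` and a
#'   list-column `recording` of [lfp_recording()] objects — one row per
#'   declared segment x channel.
#' @param params A [detection_params()].
#' @param pac_pairs List of `c(phase_band, amp_band)` pairs to run PAC on,
#'   e.g. `list(c("theta", "mid_gamma"))`; `NULL` skips PAC.
#' @param n_bins Phase bins for PAC.
#' @param notch_swr,notch_pac 60 Hz notch toggles for the two paths
#'   (defaults: on for SWR, off for PAC).
#' @return A tidy tibble: `animal_id`, `channel_id`, `genotype`, `drug`,
#'   `stimulus` (segment label), `feature_name`, `raw_value`,
#'   `baseline_normalized_value` (NA for baseline rows and non-SWR features).
#'   A run manifest (all parameters) is attached as attribute `manifest`.
#' @export
run_session <- function(design, recordings, params = detection_params(),
                        pac_pairs = list(c("theta", "mid_gamma")),
                        n_bins = 18, notch_swr = TRUE, notch_pac = FALSE) {
  stopifnot(inherits(design, "session_design"),
            is.data.frame(recordings),
            all(c("segment", "channel_id", "recording") %in% names(recordings)))
  need <- tidyr::expand_grid(segment = design$trials$segment,
                             channel_id = design$channels)
  have <- recordings[, c("segment", "channel_id")]
  missing <- dplyr::anti_join(need, have, by = c("segment", "channel_id"))
  if (nrow(missing) > 0) {
    stop("missing recording(s) for: ",
         paste(missing$segment, missing$channel_id, sep = "/", collapse = ", "),
         call. = FALSE)
  }

  rows <- purrr::map_dfr(design$channels, function(ch) {
    seg_rows <- purrr::map(design$trials$segment, function(seg) {
      rec <- recordings$recording[[
        which(recordings$segment == seg & recordings$channel_id == ch)[1]]]
      dur <- design$trials$duration_s[design$trials$segment == seg]
      ev <- detect_swr(rec, params, notch = notch_swr)
      smry <- summarize_trial(ev, dur)
      attr(smry, "channel_id") <- ch
      pac <- purrr::map(pac_pairs, function(pr) {
        pac_for_trial(rec, pr[1], pr[2], n_bins = n_bins, notch = notch_pac)
      })
      list(summary = smry, pac = pac)
    })
    names(seg_rows) <- design$trials$segment

    base <- seg_rows[["baseline"]]
    purrr::map_dfr(design$trials$segment, function(seg) {
      sm <- seg_rows[[seg]]$summary
      norm <- if (seg != "baseline" && !is.null(base)) {
        normalize_to_baseline(sm, base$summary)
      }
      swr <- tibble::tibble(
        feature_name = swr_feature_names,
        raw_value = unname(vapply(swr_feature_names, function(f) sm[[f]],
                                  numeric(1))),
        baseline_normalized_value = if (is.null(norm)) NA_real_ else
          unname(vapply(swr_feature_names, function(f) norm[[f]], numeric(1)))
      )
      pac_tbl <- purrr::map2_dfr(seg_rows[[seg]]$pac, pac_pairs, function(pr, pair) {
        tibble::tibble(
          feature_name = paste0("mi_", pair[2]),
          raw_value = attr(pr, "mi"),
          baseline_normalized_value = NA_real_
        )
      })
      dplyr::bind_rows(swr, pac_tbl) |>
        dplyr::mutate(animal_id = design$animal_id, channel_id = ch,
                      genotype = design$genotype, drug = design$drug,
                      stimulus = seg, .before = 1)
    })
  })

  manifest <- list(
    animal_id = design$animal_id,
    detection = unclass(params),
    pac = list(pairs = pac_pairs, n_bins = n_bins),
    notch = list(swr = notch_swr, pac = notch_pac),
    model_formula = "feature ~ genotype * drug + (1 | animal_id)",
    package_version = as.character(utils::packageVersion("ripplepac"))
  )
  structure(rows, manifest = manifest, class = c("tidy_lfp_results", class(rows)))
}

#' Simulate and analyze a cohort with known group effects
#'
#' Generates a full cohort — animals split evenly over the groups named in
#' `rate_multiplier` — with group-dependent stimulus ripple rates and
#' optional per-segment theta-gamma coupling, runs the session pipeline on
#' every animal, and returns both the measured tidy table and the generating
#' truth so group-level recovery can be tested.
#'
#' @param n_animals Number of animals (>= 1).
#' @param n_channels Electrodes per animal.
#' @param segments Named numeric vector of segment durations in seconds; must
#'   include `"baseline"` first, e.g. `c(baseline = 60, stimulus = 60)`.
#' @param baseline_rate_hz Injected ripple rate in the baseline segment.
#' @param rate_multiplier Named numeric vector: per-group multiplier applied
#'   to the baseline rate in non-baseline segments (all >= 0); the names
#'   define the groups (stored in the `genotype` column).
#' @param coupling Optional named numeric vector of theta-gamma coupling per
#'   segment (same names as `segments`); `NULL` disables the PAC component
#'   and PAC analysis.
#' @param amplitude_z,duration_ms Injected burst shape (detector units / ms).
#' @param fs Sampling rate (Hz).
#' @param noise A [noise_spec()] for the background.
#' @param params A [detection_params()].
#' @param drug Treatment label recorded in the tidy table.
#' @param notch_swr 60 Hz notch in the SWR path; defaults to on only when the
#'   background actually contains line contamination (`noise$line_amp > 0`).
#' @param seed Integer seed; every animal/segment derives its own substream.
#' @return A list: `results` (tidy tibble from [run_session()] rows bound over
#'   animals) and `truth` (tibble of injected rates and coupling per
#'   animal x segment).
#' @examples
#' \donttest{
#' sim <- batch_simulate_and_analyze(
#'   n_animals = 4, n_channels = 1, segments = c(baseline = 20, stimulus = 20),
#'   rate_multiplier = c(cre_only = 1, cre_gi = 2), seed = 1)
#' }
#' @export
batch_simulate_and_analyze <- function(n_animals = 10, n_channels = 2,
                                       segments = c(baseline = 60, stimulus = 60),
                                       baseline_rate_hz = 0.3,
                                       rate_multiplier = c(cre_only = 1, cre_gi = 2),
                                       coupling = NULL,
                                       amplitude_z = 5, duration_ms = 50,
                                       fs = 1000, noise = noise_spec(),
                                       params = detection_params(),
                                       drug = "vehicle",
                                       notch_swr = noise$line_amp > 0,
                                       seed = 1) {
  stopifnot(n_animals >= 1, names(segments)[1] == "baseline")
  if (any(rate_multiplier < 0)) stop("rate multipliers must be >= 0", call. = FALSE)
  groups <- names(rate_multiplier)
  if (is.null(groups)) stop("`rate_multiplier` must be named by group", call. = FALSE)
  if (!is.null(coupling) && !all(names(segments) %in% names(coupling))) {
    stop("`coupling` must name every segment", call. = FALSE)
  }

  seg_names <- names(segments)
  trials <- tibble::tibble(
    segment = seg_names,
    kind = ifelse(seg_names == "baseline", "baseline", "social"),
    stimulus = ifelse(seg_names == "baseline", "none", seg_names),
    duration_s = as.numeric(segments)
  )
  channels <- paste0("ch", seq_len(n_channels))
  group_of <- groups[((seq_len(n_animals) - 1) %% length(groups)) + 1]

  truth <- list()
  results <- purrr::map_dfr(seq_len(n_animals), function(a) {
    grp <- group_of[a]
    design <- session_design(sprintf("m%02d", a), genotype = grp, drug = drug,
                             trials = trials, channels = channels)
    recs <- purrr::map_dfr(seq_along(seg_names), function(si) {
      seg <- seg_names[si]
      rate <- if (seg == "baseline") baseline_rate_hz else
        baseline_rate_hz * rate_multiplier[[grp]]
      purrr::map_dfr(seq_len(n_channels), function(ci) {
        # independent, reproducible substream per animal x segment x channel
        sub_seed <- (seed * 100003L + a * 1009L + si * 101L + ci) %% 2147483647L
        bg <- generate_background(segments[[si]], fs, noise, seed = sub_seed,
                                  channel_id = channels[ci])
        if (!is.null(coupling)) {
          pac <- generate_pac(segments[[si]], fs,
                              pac_spec(coupling = coupling[[seg]]),
                              noise = NULL, seed = sub_seed)
          bg <- new_lfp_like(bg, bg$voltage + pac$recording$voltage)
        }
        inj <- if (rate > 0) {
          inject_ripples(bg, ripple_spec(rate = rate, duration_ms = duration_ms,
                                         amplitude_z = amplitude_z),
                         seed = sub_seed + 1L)
        } else list(recording = bg)
        tibble::tibble(segment = seg, channel_id = channels[ci],
                       recording = list(inj$recording))
      })
    })
    truth[[a]] <<- tibble::tibble(
      animal_id = design$animal_id, genotype = grp, segment = seg_names,
      true_rate_hz = ifelse(seg_names == "baseline", baseline_rate_hz,
                            baseline_rate_hz * rate_multiplier[[grp]]),
      true_coupling = if (is.null(coupling)) NA_real_ else
        as.numeric(coupling[seg_names])
    )
    run_session(design, recs, params = params, notch_swr = notch_swr,
                pac_pairs = if (is.null(coupling)) NULL else
                  list(c("theta", "mid_gamma")))
  })
  list(results = results, truth = dplyr::bind_rows(truth))
}

#' Permutation test for a two-group difference in means
#'
#' Exact enumeration of all group relabelings when feasible (up to
#' `max_exact` combinations), otherwise Monte Carlo. Two-sided on the
#' difference of group means.
#'
#' @param x Numeric values.
#' @param g Two-level group labels, same length as `x`.
#' @param n_perm Monte Carlo permutations when enumeration is infeasible.
#' @param max_exact Enumeration budget.
#' @param seed Seed for the Monte Carlo path.
#' @return A list with `statistic` (mean difference) and `p_value`.
#' @export
perm_test_two_group <- function(x, g, n_perm = 2000, max_exact = 10000,
                                seed = 1) {
  g <- as.factor(g)
  stopifnot(nlevels(g) == 2, length(x) == length(g))
  keep <- !is.na(x)
  x <- x[keep]; g <- droplevels(g[keep])
  n <- length(x)
  n1 <- sum(g == levels(g)[1])
  obs <- mean(x[g == levels(g)[1]]) - mean(x[g == levels(g)[2]])
  stat <- function(idx1) mean(x[idx1]) - mean(x[-idx1])
  if (choose(n, n1) <= max_exact) {
    combos <- utils::combn(n, n1)
    perms <- apply(combos, 2, stat)
    p <- mean(abs(perms) >= abs(obs) - 1e-12)
  } else {
    perms <- with_rng_seed(seed, replicate(n_perm, stat(sample(n, n1))))
    p <- (1 + sum(abs(perms) >= abs(obs) - 1e-12)) / (1 + n_perm)
  }
  list(statistic = obs, p_value = p)
}
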