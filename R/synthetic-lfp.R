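# Synthetic LFP generation with known ground truth: 1/f background with
# optional 60 Hz line contamination, injected ripple-band bursts whose
# z-envelope amplitude is calibrated in detector units, and theta-modulated
# gamma for phase-amplitude coupling. Every generator is a pure function of
# (parameters, seed).

# run expr under set.seed(seed) without disturbing the caller's RNG stream
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specification objects for the synthetic generators
#'
#' `noise_spec()` describes the broadband background: spectral slope
#' (power ~ 1/f^exponent), target RMS and optional 60 Hz line amplitude.
#' `ripple_spec()` describes injected ripple bursts: Poisson rate, oscillation
#' frequency within 140-220 Hz, envelope width, target peak of the
#' ripple-band z-scored envelope (in SD units of that envelope, i.e. detector
#' units), and a minimum spacing. `pac_spec()` describes theta-modulated
#' gamma: carrier and modulated frequencies, amplitudes, modulation depth
#' `coupling` in \[0, 1\], and the theta phase of maximal gamma amplitude.
#'
#' @param exponent Spectral slope (>= 0); 0 gives white noise, 1 pink.
#' @param rms Target background standard deviation (arbitrary voltage units).
#' @param line_amp Amplitude of an added 60 Hz sinusoid (0 = off).
#' @return A validated named list (`noise_spec` / `ripple_spec` / `pac_spec`).
#' @examples
#' noise_spec(exponent = 1, rms = 1)
#' ripple_spec(rate = 0.3, amplitude_z = 6)
#' pac_spec(coupling = 0.8, preferred_phase = 0)
#' @export
noise_spec <- function(exponent = 1, rms = 1, line_amp = 0) {
  stopifnot(exponent >= 0, rms > 0, line_amp >= 0)
  structure(list(exponent = exponent, rms = rms, line_amp = line_amp),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @param rate Mean burst rate (events/s, >= 0).
#' @param center_freq Burst oscillation frequency (Hz, in 140-220).
#' @param duration_ms Burst envelope full width, the +/- 3 sigma support (ms).
#' @param amplitude_z Target peak of the ripple-band z-envelope at burst
#'   centre (SD units, > 0).
#' @param min_gap_ms Minimum spacing between bursts (ms).
#' @export
ripple_spec <- function(rate = 0.3, center_freq = 180, duration_ms = 50,
                        amplitude_z = 6, min_gap_ms = 100) {
  stopifnot(rate >= 0, center_freq >= 140, center_freq <= 220,
            duration_ms > 0, amplitude_z > 0, min_gap_ms >= 0)
  structure(list(rate = rate, center_freq = center_freq,
                 duration_ms = duration_ms, amplitude_z = amplitude_z,
                 min_gap_ms = min_gap_ms),
            class = "ripple_spec")
}

#' @rdname noise_spec
#' @param theta_freq Carrier frequency (Hz, in 4-12).
#' @param gamma_freq Modulated frequency (Hz, in 50-100).
#' @param theta_amp Carrier amplitude.
#' @param gamma_amp Mean gamma amplitude.
#' @param coupling Modulation depth m in \[0, 1\].
#' @param preferred_phase Theta phase (radians, in (-pi, pi]) of maximal
#'   gamma amplitude.
#' @export
pac_spec <- function(theta_freq = 8, gamma_freq = 75, theta_amp = 1,
                     gamma_amp = 0.5, coupling = 0.5, preferred_phase = 0) {
  stopifnot(theta_freq >= 4, theta_freq <= 12,
            gamma_freq >= 50, gamma_freq <= 100,
            coupling >= 0, coupling <= 1,
            preferred_phase >= -pi, preferred_phase <= pi,
            theta_amp > 0, gamma_amp > 0)
  structure(list(theta_freq = theta_freq, gamma_freq = gamma_freq,
                 theta_amp = theta_amp, gamma_amp = gamma_amp,
                 coupling = coupling, preferred_phase = preferred_phase),
            class = "pac_spec")
}

#' Generate broadband 1/f background
#'
#' White Gaussian noise is spectrally shaped in the frequency domain
#' (amplitude scaled by f^(-exponent/2), DC removed), rescaled to the target
#' RMS exactly, and an optional 60 Hz sinusoid added. Deterministic given the
#' seed.
#'
#' @param duration_s Signal length in seconds (> 0).
#' @param fs Sampling rate in Hz; must be at least 440 so the 140-220 Hz
#'   ripple band is resolvable (default 1000).
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param channel_id,trial Passed to [lfp_recording()].
#' @return An `lfp_tbl` of `duration_s * fs` samples.
#' @examples
#' bg <- generate_background(2, fs = 1000, noise_spec(exponent = 1), seed = 1)
#' sd(bg$voltage)
#' @export
generate_background <- function(duration_s, fs = 1000, noise = noise_spec(),
                                seed = 1, channel_id = "ch1", trial = NULL) {
  stopifnot(duration_s > 0)
  if (fs < 2 * 220) {
    stop("fs = ", fs, " Hz cannot resolve the 140-220 Hz ripple band; ",
         "need fs >= 440 Hz", call. = FALSE)
  }
  n <- round(duration_s * fs)
  x <- with_rng_seed(seed, {
    w <- stats::rnorm(n)
    if (noise$exponent > 0) {
      fr <- c(0, seq_len(n - 1))
      fr <- pmin(fr, n - fr) * fs / n  # two-sided frequency axis, Hz
      shape <- c(0, fr[-1]^(-noise$exponent / 2))
      Re(stats::fft(stats::fft(w) * shape, inverse = TRUE) / n)
    } else {
      w - mean(w)
    }
  })
  x <- x * noise$rms / stats::sd(x)
  if (noise$line_amp > 0) {
    t <- (seq_len(n) - 1) / fs
    x <- x + noise$line_amp * sin(2 * pi * 60 * t)
  }
  lfp_recording(x, fs, channel_id = channel_id, trial = trial)
}

# Tukey-enveloped sinusoidal burst: duration_ms is the full support, the
# central half sits at full amplitude and cosine tapers (r = 0.5) avoid
# onset/offset filter ringing. Returns the waveform and its unit-peak
# envelope (needed for amplitude calibration).
burst_waveform <- function(center_freq, duration_ms, fs, envelope = FALSE) {
  half <- duration_ms / 2000            # seconds
  t <- seq(-half, half, by = 1 / fs)
  u <- (t + half) / (2 * half)          # position in [0, 1]
  r <- 0.5
  env <- ifelse(u < r / 2, 0.5 * (1 + cos(pi * (2 * u / r - 1))),
         ifelse(u > 1 - r / 2, 0.5 * (1 + cos(pi * (2 * (1 - u) / r - 1))), 1))
  if (envelope) return(env)
  env * sin(2 * pi * center_freq * t)
}

# ripple-band impulse response of a unit burst through the package's own
# zero-phase band-pass, with the ringing tails retained (0.5 s each side,
# far past the Butterworth decay). Because the band-pass is linear and
# time-invariant away from record boundaries, the filtered burst train is
# the superposition of shifted copies of this kernel, which lets the
# amplitude calibration avoid re-filtering per candidate amplitude.
# Deterministic in (center_freq, duration_ms, fs): memoized. Returns the
# kernel and the index of the burst centre within it.
.burst_kernel_cache <- new.env(parent = emptyenv())
burst_band_kernel <- function(center_freq, duration_ms, fs) {
  key <- paste(center_freq, duration_ms, fs, sep = "_")
  hit <- .burst_kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- burst_waveform(center_freq, duration_ms, fs)
  tail_n <- round(0.5 * fs)
  x <- c(numeric(tail_n), w, numeric(tail_n))
  y <- bandpass(lfp_recording(x, fs), "ripple")$voltage
  .burst_kernel_cache[[key]] <- list(kernel = y,
                                     center = tail_n + (length(w) + 1) / 2)
  .burst_kernel_cache[[key]]
}

#' Inject ripple-band bursts with calibrated z-amplitude
#'
#' Burst times follow a homogeneous Poisson process thinned to respect
#' `min_gap_ms`. Each burst is a `center_freq` sinusoid under a Tukey
#' (tapered-cosine, taper fraction 0.5) envelope of full width `duration_ms`:
#' the central half holds full amplitude and the cosine flanks avoid filter
#' ringing at onset/offset. The raw burst amplitude is calibrated from the
#' burst-free signal's ripple-band envelope statistics — corrected for the
#' mean/SD inflation the bursts themselves cause in trial-wide z-scoring —
#' so the z-scored envelope at the burst centre reaches `amplitude_z` on
#' average in the detector's own units.
#'
#' @param rec Background recording from [generate_background()].
#' @param spec A [ripple_spec()].
#' @param seed Integer seed for event placement.
#' @return A list with `recording` (the signal with bursts added) and
#'   `ground_truth`, a tibble (`start_s`, `end_s`, `amplitude_z`) of injected
#'   intervals, sorted and non-overlapping, with the seed and spec stored as
#'   attributes.
#' @examples
#' bg <- generate_background(10, 1000, seed = 1)
#' out <- inject_ripples(bg, ripple_spec(rate = 0.3), seed = 2)
#' nrow(out$ground_truth)
#' @export
inject_ripples <- function(rec, spec, seed = 1) {
  stopifnot(inherits(spec, "ripple_spec"))
  fs <- lfp_fs(rec)
  n <- nrow(rec)
  dur_s <- n / fs
  half_s <- spec$duration_ms / 2000
  gt_empty <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                             amplitude_z = numeric())
  if (spec$rate == 0) {
    gt <- structure(gt_empty, seed = seed, spec = spec,
                    class = c("swr_ground_truth", class(gt_empty)))
    return(list(recording = rec, ground_truth = gt))
  }
  min_gap_s <- spec$min_gap_ms / 1000
  if (1 / spec$rate < min_gap_s) {
    stop("rate ", spec$rate, " events/s cannot respect min_gap_ms = ",
         spec$min_gap_ms, call. = FALSE)
  }
  if (dur_s < 2 * half_s + 1 / spec$rate) {
    stop("recording too short to hold a burst at rate ", spec$rate, call. = FALSE)
  }

  # event centres: Poisson gaps, thinned so centre-to-centre spacing covers
  # the burst support plus min_gap
  centers <- with_rng_seed(seed, {
    k <- stats::rpois(1, spec$rate * dur_s)
    cand <- sort(stats::runif(max(k, 0), half_s, dur_s - half_s))
    keep <- numeric(0)
    last <- -Inf
    for (cc in cand) {
      if (cc - last >= 2 * half_s + min_gap_s) {
        keep <- c(keep, cc)
        last <- cc
      }
    }
    keep
  })

  if (length(centers) == 0) {
    gt <- structure(gt_empty, seed = seed, spec = spec,
                    class = c("swr_ground_truth", class(gt_empty)))
    return(list(recording = rec, ground_truth = gt))
  }

  # calibrate the raw amplitude so the z-scored ripple-band envelope at the
  # burst centres averages amplitude_z in the units the detector actually
  # uses — trial-wide z-scoring of the burst-containing signal, so the
  # mean/SD inflation the bursts themselves cause is folded in. The band-pass
  # and analytic transform are both linear, so with A0 the analytic
  # ripple-band background and AB the analytic ripple-band unit-amplitude
  # burst train, the envelope at burst amplitude a is |A0 + a*AB| to
  # numerical accuracy; the calibration equation
  #   mean(env[centres]) = mean(env) + amplitude_z * sd(env)
  # is solved on that empirical envelope, not on a moment model.
  w <- burst_waveform(spec$center_freq, spec$duration_ms, fs)
  half_n <- (length(w) - 1) / 2
  ctr_idx <- round(centers * fs) + 1
  train <- numeric(n)
  for (ci in ctr_idx) {
    idx <- (ci - half_n):(ci + half_n)
    ok <- idx >= 1 & idx <= n
    train[idx[ok]] <- train[idx[ok]] + w[ok]
  }
  A0 <- analytic_signal(bandpass(rec, "ripple")$voltage)
  kern <- burst_band_kernel(spec$center_freq, spec$duration_ms, fs)
  yB <- numeric(n)
  for (ci in ctr_idx) {
    idx <- (ci - kern$center + 1):(ci - kern$center + length(kern$kernel))
    ok <- idx >= 1 & idx <= n
    yB[idx[ok]] <- yB[idx[ok]] + kern$kernel[ok]
  }
  AB <- analytic_signal(yB)
  excess_z <- function(a) {
    e <- Mod(A0 + a * AB)
    mean(e[ctr_idx]) - (mean(e) + spec$amplitude_z * stats::sd(e))
  }
  env0 <- Mod(A0)
  upper <- 10 * (mean(env0) + spec$amplitude_z * stats::sd(env0))
  amp_raw <- tryCatch(
    stats::uniroot(excess_z, c(0, upper), extendInt = "upX", tol = 1e-6)$root,
    error = function(e) {
      stop("amplitude_z = ", spec$amplitude_z, " is unreachable at rate ",
           spec$rate, " events/s: the bursts occupy so much of the trial ",
           "that they inflate the trial-wide envelope SD faster than they ",
           "raise the centre envelope; lower rate or amplitude_z",
           call. = FALSE)
    })
  x <- rec$voltage + amp_raw * train
  gt <- tibble::tibble(
    start_s = centers - half_s,
    end_s = centers + half_s,
    amplitude_z = rep(spec$amplitude_z, length(centers))
  )
  gt <- structure(gt, seed = seed, spec = spec,
                  class = c("swr_ground_truth", class(gt)))
  list(recording = new_lfp_like(rec, x), ground_truth = gt)
}

#' Generate a theta-modulated gamma signal
#'
#' The deterministic part is
#' `theta_amp * sin(2 pi f_theta t) +
#'  gamma_amp * (1 + coupling * cos(phi(t) - preferred_phase)) / 2 *
#'  sin(2 pi f_gamma t)`,
#' where `phi(t) = 2 pi f_theta t - pi/2` is the carrier's instantaneous
#' phase in the cosine convention (phase 0 at the theta positive peak) — the
#' same convention [analytic()] measures — so the theta phase of maximal
#' gamma amplitude equals `preferred_phase` exactly. The 1/f background of
#' `noise` is added (`noise = NULL` for none).
#'
#' @inheritParams generate_background
#' @param spec A [pac_spec()].
#' @param noise A [noise_spec()] or `NULL` for a noise-free signal.
#' @return A list with `recording` (an `lfp_tbl`) and `ground_truth` (the
#'   spec, noise and seed).
#' @examples
#' out <- generate_pac(12, 1000, pac_spec(coupling = 1), noise = NULL, seed = 1)
#' @export
generate_pac <- function(duration_s, fs = 1000, spec = pac_spec(),
                         noise = noise_spec(), seed = 1,
                         channel_id = "ch1", trial = NULL) {
  stopifnot(inherits(spec, "pac_spec"))
  if (duration_s < 10) {
    warning("duration_s < 10 s gives unstable phase-bin estimates", call. = FALSE)
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  th_phase <- 2 * pi * spec$theta_freq * t
  # cosine-convention phase of the sin carrier is th_phase - pi/2
  x <- spec$theta_amp * sin(th_phase) +
    spec$gamma_amp *
      (1 + spec$coupling * cos(th_phase - pi / 2 - spec$preferred_phase)) / 2 *
      sin(2 * pi * spec$gamma_freq * t)
  if (!is.null(noise)) {
    bg <- generate_background(duration_s, fs, noise, seed)
    x <- x + bg$voltage
  }
  rec <- lfp_recording(x, fs, channel_id = channel_id, trial = trial)
  list(recording = rec,
       ground_truth = list(pac = spec, noise = noise, seed = seed))
}
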