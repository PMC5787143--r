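# Synthetic intramuscular EMG generation: Hermite-Rodriguez MUAP templates,
# stationary-renewal firing patterns with optional uniform random discharges,
# and band-limited Gaussian noise at a configurable SNR.

REFRACTORY_S <- 0.003  # absolute refractory floor between discharges of one MU

# Physicists' Hermite polynomials H_0..H_(n-1) evaluated at tau (matrix cols).
hermite_basis <- function(tau, n_terms) {
  H <- matrix(0, length(tau), n_terms)
  H[, 1] <- 1
  if (n_terms > 1L) H[, 2] <- 2 * tau
  if (n_terms > 2L) {
    for (j in 3:n_terms) {
      H[, j] <- 2 * tau * H[, j - 1] - 2 * (j - 2) * H[, j - 2]
    }
  }
  H
}

#' Synthesize a MUAP template waveform
#'
#' Draws a motor unit action potential shape as a 16-term Hermite-Rodriguez
#' expansion (Hermite polynomials under a Gaussian envelope) with random
#' coefficients whose magnitudes decay geometrically away from the order that
#' produces the requested phase count. The draw is repeated until the phase
#' counter ([count_phases()], at 10% of the peak amplitude) reports exactly
#' `n_phases_target` phases.
#'
#' @param duration_ms Template duration in milliseconds (>= 1.5).
#' @param amplitude_uv Peak absolute amplitude in microvolts (> 0).
#' @param n_phases_target Desired number of phases (1-8; 2-4 is the healthy
#'   range, up to 6 for pathological re-innervated units).
#' @param fs Sampling rate in Hz.
#' @param mu_id Integer label carried by the template.
#' @param max_tries Redraws allowed before giving up (the parameter
#'   combination is then reported as unreachable).
#' @return Object of class `muap_template`: `mu_id`, `waveform` (uV),
#'   `peak_index` (1-based argmax of |waveform|, first occurrence on ties),
#'   `n_phases`, `fs`.
#' @export
make_template <- function(duration_ms, amplitude_uv, n_phases_target, fs,
                          mu_id = 1L, max_tries = 100L) {
  if (duration_ms < 1.5) stop("duration_ms must be >= 1.5")
  if (fs <= 0) stop("fs must be positive")
  if (!is.finite(amplitude_uv) || amplitude_uv <= 0) stop("amplitude_uv must be > 0")
  if (n_phases_target < 1 || n_phases_target > 8) stop("n_phases_target must be in 1..8")
  n <- round(duration_ms / 1000 * fs)
  n_terms <- 16L
  tau <- seq(-4.5, 4.5, length.out = n)
  B <- hermite_basis(tau, n_terms) * exp(-tau^2 / 2)
  B <- sweep(B, 2, apply(abs(B), 2, max), "/")
  # raised-cosine taper over the outer 10% so the template starts/ends at zero
  ntap <- max(2L, round(0.1 * n))
  taper <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = ntap)))
  taper[seq_len(ntap)] <- ramp
  taper[n - seq_len(ntap) + 1L] <- ramp
  decay <- 0.35
  order_weight <- decay^abs(seq_len(n_terms) - n_phases_target)
  for (try in seq_len(max_tries)) {
    coef <- stats::runif(n_terms, -1, 1) * order_weight
    w <- drop(B %*% coef) * taper
    m <- max(abs(w))
    if (m == 0) next
    w <- w * (amplitude_uv / m)
    # the phase count must be stable over the operating range of detection
    # thresholds (roughly 5-25% of the peak for realistic SNR and k): every
    # baseline excursion clearly above a quarter of the peak or clearly
    # below 5%, so noise-level threshold shifts cannot flip the count
    np <- count_phases(w, threshold = 0.1 * amplitude_uv)
    ext <- sort(abs(phase_extrema(w, 0.1 * amplitude_uv)), decreasing = TRUE)
    dominant <- length(ext) < 2L || ext[2] <= 0.75 * ext[1]
    if (np == n_phases_target && dominant &&
        count_phases(w, threshold = 0.05 * amplitude_uv) == np &&
        count_phases(w, threshold = 0.25 * amplitude_uv) == np) {
      return(structure(list(mu_id = as.integer(mu_id), waveform = w,
                            peak_index = which.max(abs(w)),
                            n_phases = np, fs = fs),
                       class = "muap_template"))
    }
  }
  stop("could not synthesize a ", n_phases_target, "-phase template of ",
       duration_ms, " ms in ", max_tries, " draws; ",
       "invalid parameter combination")
}

#' Generate a motor unit firing pattern
#'
#' Discharge times follow a stationary-renewal process with Gaussian
#' inter-pulse intervals (mean `1/mean_rate_hz`, standard deviation
#' `ipi_cv/mean_rate_hz`, truncated below at the 3 ms refractory floor),
#' merged with a Poisson number of extra discharges at uniform random
#' positions. Times closer than the refractory floor to a kept discharge are
#' dropped.
#'
#' @param duration_s Record duration in seconds (> 0).
#' @param mean_rate_hz Mean firing rate in pulses per second, in (0, 50].
#' @param ipi_cv Coefficient of variation of the inter-pulse interval, in
#'   \[0, 0.5\].
#' @param random_rate_hz Rate of additional uniformly placed discharges
#'   (per second).
#' @param mu_id Integer label.
#' @return Object of class `firing_pattern`: `mu_id`, `times` (strictly
#'   increasing, seconds), `mean_ipi`, `ipi_cv`, `random_rate`.
#' @export
make_firing_pattern <- function(duration_s, mean_rate_hz, ipi_cv = 0.15,
                                random_rate_hz = 0, mu_id = 1L) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (mean_rate_hz <= 0 || mean_rate_hz > 50) stop("mean_rate_hz must be in (0, 50]")
  if (ipi_cv < 0 || ipi_cv > 0.5) stop("ipi_cv must be in [0, 0.5]")
  mean_ipi <- 1 / mean_rate_hz
  sd_ipi <- ipi_cv * mean_ipi
  draw_ipi <- function() {
    if (sd_ipi == 0) return(mean_ipi)
    repeat {
      v <- stats::rnorm(1, mean_ipi, sd_ipi)
      if (v >= REFRACTORY_S) return(v)
    }
  }
  t <- stats::runif(1, 0, mean_ipi)
  times <- numeric(0)
  while (t < duration_s) {
    times <- c(times, t)
    t <- t + draw_ipi()
  }
  n_extra <- stats::rpois(1, random_rate_hz * duration_s)
  if (n_extra > 0) times <- c(times, stats::runif(n_extra, 0, duration_s))
  times <- sort(times)
  if (length(times) > 1) {
    keep <- c(TRUE, diff(times) >= REFRACTORY_S)
    while (!all(keep)) {  # re-check spacing after drops
      times <- times[keep]
      keep <- c(TRUE, diff(times) >= REFRACTORY_S)
    }
  }
  structure(list(mu_id = as.integer(mu_id), times = times, mean_ipi = mean_ipi,
                 ipi_cv = ipi_cv, random_rate = random_rate_hz),
            class = "firing_pattern")
}

# Sum template copies placed at 1-based onset samples into a length-N vector.
place_train <- function(waveform, onsets, N) {
  x <- numeric(N)
  m <- length(waveform)
  for (o in onsets) {
    x[o:(o + m - 1L)] <- x[o:(o + m - 1L)] + waveform
  }
  x
}

#' Render a synthetic EMG record from templates and firing patterns
#'
#' The clean signal is the sum over motor units of the template waveform
#' placed at each firing time (the firing time marks the template's first
#' sample). Additive noise is Gaussian white noise band-passed to
#' `noise_band` and scaled so that `10*log10(P_clean/P_noise)` equals
#' `snr_db` exactly (mean-square power over the whole record). Firings whose
#' waveform would be clipped by the record end are dropped from both the
#' signal and the returned ground truth.
#'
#' @param templates List of [make_template()] objects.
#' @param patterns List of [make_firing_pattern()] objects, one per template,
#'   matched by `mu_id`.
#' @param duration_s,fs Record duration (s) and sampling rate (Hz).
#' @param snr_db Signal-to-noise ratio in dB; `Inf` disables noise.
#' @param background_mus Number of extra low-amplitude (8-25 uV) motor units
#'   added as unscored background activity, emulating the biological noise
#'   floor left behind after all scored MUAPs are accounted for.
#' @param noise_band Pass band of the noise, Hz.
#' @return List with `record` (an [emg_record()]) and `truth` (class
#'   `emg_ground_truth`: `templates`, `patterns` with the rendered times,
#'   `snr_db`, `fs`, `duration_s`).
#' @export
synthesize_emg <- function(templates, patterns, duration_s = 5, fs = 30000,
                           snr_db = 20, background_mus = 0,
                           noise_band = c(100, 10000)) {
  stopifnot(length(templates) == length(patterns))
  ids_t <- vapply(templates, `[[`, integer(1), "mu_id")
  ids_p <- vapply(patterns, `[[`, integer(1), "mu_id")
  if (!identical(sort(ids_t), sort(ids_p))) stop("template/pattern mu_id mismatch")
  patterns <- patterns[match(ids_t, ids_p)]
  N <- round(duration_s * fs)
  clean <- numeric(N)
  for (i in seq_along(templates)) {
    m <- length(templates[[i]]$waveform)
    onsets <- round(patterns[[i]]$times * fs) + 1L
    keep <- onsets >= 1L & (onsets + m - 1L) <= N
    onsets <- onsets[keep]
    patterns[[i]]$times <- (onsets - 1L) / fs
    clean <- clean + place_train(templates[[i]]$waveform, onsets, N)
  }
  x <- clean
  if (background_mus > 0) {
    for (b in seq_len(background_mus)) {
      bt <- make_template(stats::runif(1, 3, 6), stats::runif(1, 8, 25),
                          sample(2:4, 1), fs, mu_id = -b)
      bp <- make_firing_pattern(duration_s, stats::runif(1, 8, 15), 0.15, mu_id = -b)
      onsets <- round(bp$times * fs) + 1L
      onsets <- onsets[onsets + length(bt$waveform) - 1L <= N]
      x <- x + place_train(bt$waveform, onsets, N)
    }
  }
  if (is.finite(snr_db)) {
    p_clean <- mean(clean^2)
    if (p_clean == 0) stop("cannot set an SNR on an identically zero clean signal")
    noise <- stats::rnorm(N)
    bf <- signal::butter(4, noise_band / (fs / 2), type = "pass")
    noise <- signal::filtfilt(bf, noise)
    noise <- noise * sqrt(p_clean / 10^(snr_db / 10) / mean(noise^2))
    x <- x + noise
  }
  truth <- structure(list(templates = templates, patterns = patterns,
                          snr_db = snr_db, fs = fs, duration_s = duration_s),
                     class = "emg_ground_truth")
  list(record = emg_record(x, fs), truth = truth)
}

#' Simulate a complete synthetic EMG recording
#'
#' High-level generator emulating the study conditions: a 5-s, 30 kHz
#' single-channel recording of `n_mus` motor units firing by a
#' stationary-renewal process, corrupted by 100 Hz-10 kHz band-passed
#' Gaussian noise. Template shapes are redrawn until every pair is separated
#' by at least `min_template_distance` in the wavelet feature space (the
#' clustering distance, [muap_distance()]), so that the units are genuinely
#' distinct sources.
#'
#' @param n_mus Number of motor units (3-8 is typical).
#' @param duration_s,fs,snr_db See [synthesize_emg()].
#' @param rate_range Per-MU mean firing rates drawn uniformly from this range
#'   (pulses per second).
#' @param ipi_cv Inter-pulse-interval coefficient of variation.
#' @param random_rate_hz Extra uniform discharges per second per MU.
#' @param amplitude_range Peak amplitudes (uV) drawn uniformly.
#' @param duration_ms_range Template durations (ms) drawn uniformly.
#' @param n_phases_range Integer range of template phase counts.
#' @param min_template_distance Minimum pairwise template distance in feature
#'   space (0 disables the separation constraint).
#' @param background_mus Extra sub-threshold background units.
#' @param seed Optional integer seed for full reproducibility.
#' @return As [synthesize_emg()].
#' @export
simulate_emg <- function(n_mus = 6, duration_s = 5, fs = 30000, snr_db = 20,
                         rate_range = c(8, 15), ipi_cv = 0.15,
                         random_rate_hz = 0, amplitude_range = c(150, 600),
                         duration_ms_range = c(3, 6), n_phases_range = c(2, 4),
                         min_template_distance = 0.3, background_mus = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  templates <- list()
  for (i in seq_len(n_mus)) {
    for (try in seq_len(60L)) {
      tpl <- make_template(stats::runif(1, duration_ms_range[1], duration_ms_range[2]),
                           stats::runif(1, amplitude_range[1], amplitude_range[2]),
                           sample(seq(n_phases_range[1], n_phases_range[2]), 1),
                           fs, mu_id = i, max_tries = 1000L)
      if (min_template_distance <= 0 || length(templates) == 0) break
      dmin <- min(vapply(templates, function(o)
        template_feature_distance(o$waveform, tpl$waveform), numeric(1)))
      if (dmin >= min_template_distance) break
      if (try == 60L) stop("could not draw ", n_mus,
                           " templates with pairwise feature distance >= ",
                           min_template_distance)
    }
    templates[[i]] <- tpl
  }
  patterns <- lapply(seq_len(n_mus), function(i)
    make_firing_pattern(duration_s, stats::runif(1, rate_range[1], rate_range[2]),
                        ipi_cv, random_rate_hz, mu_id = i))
  out <- synthesize_emg(templates, patterns, duration_s, fs, snr_db, background_mus)
  out$truth$seed <- seed
  out
}

# Eq-3 feature distance between two raw template waveforms, computed on a
# common peak-centred power-of-two support.
template_feature_distance <- function(w1, w2) {
  al <- align_waveforms(list(w1, w2))
  F <- extract_features(al)
  muap_distance(F[1, ], F[2, ])
}
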